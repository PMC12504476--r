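# A tiny 2-primary / 5-secondary schema for unit tests.
tiny_schema <- function() {
  pmc_schema("tiny", list(
    list(index = 1, label = "Alpha", secondaries = list(
      list(id = "X11", label = "a1", criterion = "is a1"),
      list(id = "X12", label = "a2", criterion = "is a2"))),
    list(index = 2, label = "Beta", secondaries = list(
      list(id = "X21", label = "b1", criterion = "is b1"),
      list(id = "X22", label = "b2", criterion = "is b2"),
      list(id = "X23", label = "b3", criterion = "is b3")))))
}

tiny_scores <- function() {
  pmc_score_table(tibble::tibble(
    policy = c("A", "B"),
    X11 = c(1, 0), X12 = c(1, 0),
    X21 = c(1, 1), X22 = c(0, 1), X23 = c(1, 0)), tiny_schema())
}

# The bundled 10-policy bitstrings, inlined as printed, for oracle use.
printed_bits <- function() {
  list(
    P1 = c("111", "111", "110", "111", "11111", "1111", "111", "11111", "1111"),
    P2 = c("111", "111", "011", "101", "01110", "1111", "111", "11101", "1110"),
    P3 = c("101", "111", "001", "111", "11110", "1111", "111", "01111", "1110"),
    P4 = c("101", "111", "100", "001", "01110", "1111", "111", "01111", "1010"),
    P5 = c("101", "111", "001", "101", "01110", "1111", "111", "01111", "1111"),
    P6 = c("111", "111", "011", "111", "11110", "1111", "111", "11111", "1111"),
    P7 = c("101", "111", "101", "011", "01110", "1111", "111", "01111", "1010"),
    P8 = c("101", "111", "001", "011", "01110", "1111", "111", "00111", "1110"),
    P9 = c("101", "111", "101", "111", "01110", "1111", "111", "11111", "1111"),
    P10 = c("101", "111", "001", "011", "11110", "1111", "111", "01111", "1110"))
}

# Independent brute-force oracle: primary scores and index straight from the
# bitstrings, rounding with an arithmetic formulation separate from the
# package's helper.
oracle_scores <- function(bits, rounded = TRUE) {
  sapply(bits, function(s) {
    b <- as.integer(strsplit(s, "")[[1]])
    x <- sum(b) / length(b)
    if (rounded) trunc(x * 100 + 0.5) / 100 else x
  }, USE.NAMES = FALSE)
}

expect_valid_error <- function(expr) {
  expect_error(expr, class = "pmcindex_validation_error")
}
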