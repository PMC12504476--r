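name: smart-eldercare-policy
primaries:
  - index: 1
    label: Policy Nature
    secondaries:
      - id: X11
        label: Supervision
        criterion: >-
          Judge whether the policy involves supervision in development.
          If it is, then it scores 1; if not, then it scores 0.
      - id: X12
        label: Prediction
        criterion: >-
          Judge whether the policy involves a description of future development
          results. If it is, then it scores 1; if not, then it scores 0.
      - id: X13
        label: Guidance
        criterion: >-
          Judge whether the policy involves the guiding goals of development.
          If it is, then it scores 1; if not, then it scores 0.
  - index: 2
    label: Policy Area
    secondaries:
      - id: X21
        label: Economy
        criterion: >-
          Judge whether the policy involves an economic area.
          If it is, then it scores 1; if not, then it scores 0.
      - id: X22
        label: Medicine
        criterion: >-
          Judge whether the policy involves a medical area.
          If it is, then it scores 1; if not, then it scores 0.
      - id: X23
        label: Technology
        criterion: >-
          Judge whether the policy involves a technology area.
          If it is, then it scores 1; if not, then it scores 0.
  - index: 3
    label: Policy Timeliness
    secondaries:
      - id: X31
        label: Long term
        criterion: >-
          Judge whether the policy covers more than 5 years.
          If it is, then it scores 1; if not, then it scores 0.
      - id: X32
        label: Mid-term
        criterion: >-
          Judge whether the policy covers 3-5 year content.
          If it is, then it scores 1; if not, then it scores 0.
      - id: X33
        label: Short-term
        criterion: >-
          Judge whether the policy covers up to 3 years.
          If it is, then it scores 1; if not, then it scores 0.
  - index: 4
    label: Policy Aim
    secondaries:
      - id: X41
        label: Product Development
        criterion: >-
          Judge whether the policy aim involves the development of products that
          meet the needs of the older adults. If it is, then it scores 1;
          if not, then it scores 0.
      - id: X42
        label: Publicity and Promotion
        criterion: >-
          Judge whether the policy aim involves publicizing and promoting older
          adults services. If it is, then it scores 1; if not, then it scores 0.
      - id: X43
        label: Service Supply Optimization
        criterion: >-
          Judge whether the policy aim involves optimizing service provision.
          If it is, then it scores 1; if not, then it scores 0.
  - index: 5
    label: Policy Content
    secondaries:
      - id: X51
        label: Application Pilot
        criterion: >-
          Judge whether the policy involves the content of application pilot.
          If it is, then it scores 1; if not, then it scores 0.
      - id: X52
        label: Technical Training
        criterion: >-
          Judge whether the policy involves the content of technical training or
          education for the older adults. If it is, then it scores 1;
          if not, then it scores 0.
      - id: X53
        label: Government Subsidy
        criterion: >-
          Judge whether the policy involves the content of government subsidies.
          If it is, then it scores 1; if not, then it scores 0.
      - id: X54
        label: Smart Device
        criterion: >-
          Judge whether the policy involves the content of smart devices.
          If it is, then it scores 1; if not, then it scores 0.
      - id: X55
        label: Network Security
        criterion: >-
          Judge whether the policy involves the content of network security.
          If it is, then it scores 1; if not, then it scores 0.
  - index: 6
    label: Policy Object
    secondaries:
      - id: X61
        label: Government
        criterion: >-
          Judge whether the policy object involves government.
          If it is, then it scores 1; if not, then it scores 0.
      - id: X62
        label: Business Unit
        criterion: >-
          Judge whether the policy object involves business units.
          If it is, then it scores 1; if not, then it scores 0.
      - id: X63
        label: Community
        criterion: >-
          Judge whether the policy object involves community.
          If it is, then it scores 1; if not, then it scores 0.
      - id: X64
        label: Household
        criterion: >-
          Judge whether the policy object involves household.
          If it is, then it scores 1; if not, then it scores 0.
  - index: 7
    label: Policy Evaluation
    secondaries:
      - id: X71
        label: Sufficient Basis
        criterion: >-
          Judge whether the policy basis is sufficient.
          If it is, then it scores 1; if not, then it scores 0.
      - id: X72
        label: Planning Details
        criterion: >-
          Judge whether the policy is planned in detail.
          If it is, then it scores 1; if not, then it scores 0.
      - id: X73
        label: Scheme Science
        criterion: >-
          Judge whether the scheme of the policy is scientific.
          If it is, then it scores 1; if not, then it scores 0.
  - index: 8
    label: Policy Measure
    secondaries:
      - id: X81
        label: Institutional Reform
        criterion: >-
          Judge whether the policy involves institutional reforms to build
          specialized institutions for the older adults. If it is, then it
          scores 1; if not, then it scores 0.
      - id: X82
        label: Financial Support
        criterion: >-
          Judge whether the policy involves financial support.
          If it is, then it scores 1; if not, then it scores 0.
      - id: X83
        label: Cultivation of Talent
        criterion: >-
          Judge whether the policy involves talent training.
          If it is, then it scores 1; if not, then it scores 0.
      - id: X84
        label: Legal Safeguards
        criterion: >-
          Judge whether the policy involves legal safeguards.
          If it is, then it scores 1; if not, then it scores 0.
      - id: X85
        label: Assessment and Evaluation
        criterion: >-
          Judge whether the policy involves assessment and evaluation.
          If it is, then it scores 1; if not, then it scores 0.
  - index: 9
    label: Policy Tool
    secondaries:
      - id: X91
        label: Compulsory Type
        criterion: >-
          Judge whether the policy specifies that certain behaviors are
          prohibited or permitted. If it is, then it scores 1;
          if not, then it scores 0.
      - id: X92
        label: Innovative Type
        criterion: >-
          Judge whether the policy involves the integration of technological and
          institutional innovation or industrial innovation. If it is, then it
          scores 1; if not, then it scores 0.
      - id: X93
        label: Market Type
        criterion: >-
          Judge whether the policy gives full play to the role of market
          resource allocation. If it is, then it scores 1; if not, then it
          scores 0.
      - id: X94
        label: Cooperative Type
        criterion: >-
          Judge whether the policy involves international cooperation.
          If it is, then it scores 1; if not, then it scores 0.
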