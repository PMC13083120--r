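# MRIRA annotation scheme: 16 entity types, 11 event types, 5 event
# attributes, 9 relation types (10 endpoint constraints), 6 argument roles.
# Canonical entity spellings follow the relation-constraint table; variant
# spellings used elsewhere are registered as aliases.
name: MRIRA
entity_types:
  general:
    - People
    - Location
    - Date/Time
    - Artefact
    - Knowledge
    - Function
  patient_specific:
    - Age group
    - Gender
  domain_specific:
    - Drug name
    - Drug form
    - Drug strength or amount
    - Drug dose
    - Drug frequency
    - Dose route
    - Dose duration
    - Medical condition
event_types:
  main:
    - Prescribing
    - Transcription
    - Dispensing
    - Administration
    - Monitoring
  supplementary:
    - Corrective action
    - Preventive action
    - Underlying and contributing factors
    - Error outcome
    - Action taken
    - Other action
attribute_names:
  - Action intended and actual
  - Action not intended but actual
  - Action intended but not actual
  - Action intent not clear
  - Negated
# the four intent/actuality attributes are mutually exclusive on one event
intent_attributes:
  - Action intended and actual
  - Action not intended but actual
  - Action intended but not actual
  - Action intent not clear
argument_roles:
  - Agent
  - Subject
  - Receiver
  - When
  - Where
  - For
relations:
  - name: has dose
    source: Drug name
    target: Drug dose
  - name: has frequency
    source: Drug dose
    target: Drug frequency
  - name: has frequency
    source: Drug name
    target: Drug frequency
  - name: has form
    source: Drug name
    target: Drug form
  - name: has route
    source: Drug name
    target: Dose route
  - name: has duration
    source: Drug name
    target: Dose duration
  - name: has strength or amount
    source: Drug name
    target: Drug strength or amount
  - name: has time
    source: Drug dose
    target: Date/Time
  - name: has
    source: People
    target: Medical condition
  - name: at
    source: People
    target: Location
# optional event-to-event discrepancy link (e.g. prescribed oral,
# administered IV); off by default and never counted among the relations
mismatch_link:
  name: Mismatch
  enabled: false
aliases:
  Dosage form: Drug form
  Strength or amount: Drug strength or amount
  Dose: Drug dose
  Frequency: Drug frequency
  Dose frequency: Drug frequency
  Route of administration: Dose route
  Duration: Dose duration
  Patient age: Age group
  Date or time: Date/Time
  Underlying or contributing factor: Underlying and contributing factors
  Underlying contributing factor: Underlying and contributing factors
  Other actions: Other action
  Has dose: has dose
  Has frequency: has frequency
  Has form: has form
  Has route: has route
  Has duration: has duration
  Has strength or amount: has strength or amount
  Has time: has time
  Has: has
  At: at
  has medical condition: has
  Error-intended-but-not-actual: Action intended but not actual
  Error-not-intended-but-actual: Action not intended but actual
  Error-intended-and-actual: Action intended and actual
  Error-intent-not-clear: Action intent not clear
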