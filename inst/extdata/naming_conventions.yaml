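# File-name prefix -> entity type convention used by infer_entity_type().
# Editable: capturers may ship their own table.
prefixes:
  reference: Reference
  question: ResearchQuestion
  requirement: Requirement
  assumption: Assumption
  qualitative: QualitativeModel
  data: Data
  model: SimulationModel
  experiment: SimulationExperiment
  script: Script
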