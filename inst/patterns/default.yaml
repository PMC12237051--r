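# Default provenance patterns for the eight simulation-study activities.
#
# Only SpecifyingSimulationExperiment is fully prescribed by the provenance
# model's worked pattern (always uses a simulation model; optionally an
# existing experiment, an assumption and/or a requirement; always generates
# a simulation experiment). The remaining seven are reconstructed from the
# entity/activity taxonomy and the worked example graphs; they are marked
# "reconstructed" below and can be replaced by user-supplied files.
#
# Defaults applied at load time: min 0, max unbounded, required_attributes
# [name, path] for every entity, agent required with required_attributes
# [name].
patterns:
  - activity: SpecifyingReference            # reconstructed
    uses: []
    generates:
      - {entity: Reference, min: 1}
  - activity: SpecifyingResearchQuestion     # reconstructed
    uses:
      - {entity: Reference, min: 0}
    generates:
      - {entity: ResearchQuestion, min: 1}
  - activity: SpecifyingRequirement          # reconstructed
    uses:
      - {entity: Reference, min: 0}
      - {entity: ResearchQuestion, min: 0}
    generates:
      - {entity: Requirement, min: 1}
  - activity: SpecifyingAssumption           # reconstructed
    uses:
      - {entity: Reference, min: 0}
      - {entity: ResearchQuestion, min: 0}
    generates:
      - {entity: Assumption, min: 1}
  - activity: SpecifyingSimulationModel      # reconstructed
    uses:
      - {entity: Assumption, min: 0}
      - {entity: Requirement, min: 0}
      - {entity: QualitativeModel, min: 0}
      - {entity: Data, min: 0}
      - {entity: Reference, min: 0}
      - {entity: SimulationModel, min: 0}
    generates:
      - {entity: SimulationModel, min: 1}
  - activity: SpecifyingSimulationExperiment
    uses:
      - {entity: SimulationModel, min: 1}
      - {entity: SimulationExperiment, min: 0}
      - {entity: Assumption, min: 0,
         required_attributes: [name, path], optional_attributes: [specification]}
      - {entity: Requirement, min: 0,
         required_attributes: [name, path], optional_attributes: [specification]}
    generates:
      - {entity: SimulationExperiment, min: 1}
  - activity: ExecutingSimulationExperiment  # reconstructed
    uses:
      - {entity: SimulationExperiment, min: 1}
      - {entity: SimulationModel, min: 1}
      - {entity: Requirement, min: 0}
      - {entity: Data, min: 0}
    generates:
      - {entity: SimulationData, min: 1}
  - activity: AnalyzingSimulationData        # reconstructed
    uses:
      - {entity: SimulationData, min: 1}
      - {entity: Script, min: 0}
    generates:
      - {entity: Visualization, min: 1}
      - {entity: Data, min: 0}
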