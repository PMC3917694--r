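# Example analysis configuration for the passerclock CLI wrapper.
# Paths are relative to where you run the command.
alignment: alignment.nex        # NEXUS with charset blocks (or FASTA)
rootScenario: wide              # narrow | wide | uncalibrated
clock: IGR                      # strict | IGR | TK02 | select
nGenerations: 8000
sampleEvery: 10
nRuns: 2
seed: 1
doGeneEval: false
geneLengths: {MOS: 62, MYC: 50, GAPDH: 42, MB: 80, ODC1: 75, RAG1: 295, RAG2: 115}
codingFlags: {MOS: true, MYC: true, GAPDH: false, MB: false, ODC1: false, RAG1: true, RAG2: true}
calibrations:
  root: {min: 52, max: 85}
  nodes:
    - {name: Meliphagidae, offset: 10.4, mean: 58, clade: [Oscine01, Oscine02]}
    - {name: Orthonychidae, offset: 16.3, mean: 58, clade: [Oscine03, Oscine04]}
    - {name: Cracticidae, offset: 16.3, mean: 58, clade: [Oscine05, Oscine06]}
    - {name: Oriolidae, offset: 16.3, mean: 58, clade: [Oscine07, Oscine08]}
    - {name: Certhioidea, offset: 18.0, mean: 58, clade: [Oscine09, Oscine10]}
  constraints:
    Passeres: [Suboscine01, Suboscine02, Suboscine03, Oscine01, Oscine02,
               Oscine03, Oscine04, Oscine05, Oscine06, Oscine07, Oscine08,
               Oscine09, Oscine10]
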