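# Default analysis: packaged pyroglutamine exposure vs COVID-19 outcome.
exposure: pyroglutamine_exposure
outcome: covid19_outcome
n_boot: 1000
n_sim: 1000
seed: 20221011
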