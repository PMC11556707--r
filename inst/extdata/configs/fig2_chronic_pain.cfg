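# Persistent pain belief (A_hat = 1) with low vs elevated sensory noise
scenario = chronic_pain
seed = 1
A_hat = 1
n_replicates = 100
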