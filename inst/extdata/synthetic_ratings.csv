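individual,trial,cue,temperature,expected_rating,pain_rating
1,1,low,47,28.5,35.0
1,2,high,48,61.0,58.2
2,1,low,48,30.1,49.7
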