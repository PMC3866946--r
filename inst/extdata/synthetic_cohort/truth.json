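{"beta0":-2.78674615009453,"beta1":0.423743644926571,"seed":42,"achieved_rates":{"low":0.286000000003833,"high":0.529999999996016}}
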