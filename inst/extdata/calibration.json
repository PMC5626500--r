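{"scales":{"s_exc":0.331309160789935,"s_inh":0.917004043204671,"s_goc":6.72717132202972},"achieved":{"grc_hz":1.02901754385965,"goc_hz":7.88771929824561,"grc_noinh_hz":6.28771052631579},"residuals":{"grc":0.0188292513461872,"goc":-0.0357311371337881,"grc_noinh":0.0375759944415495},"seed":1,"gmax_ns":{"ampa_grc":0.106018931452779,"nmda_grc":0.298178244710942,"gaba_grc":0.385141698145962,"ampa_mf_goc":2.3545099627104,"ampa_aa_goc":0.0807260558643566,"ampa_pf_goc":0.0403630279321783}}
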