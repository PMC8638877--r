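{"participant_id":"example","age_months":24,"visit":1,"variant":"ECITT_S1","counterbalance":"top","seed":42,"software_version":"0.1.0"}
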