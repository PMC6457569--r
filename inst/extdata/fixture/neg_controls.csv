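control_id,control_type,m_total,m_pos
NC01,field,17000,0
NC02,field,17000,0
NC03,field,17000,0
NC04,filtration,17000,0
NC05,extraction,17000,0
NC06,NTC,17000,0
NC07,NTC,17000,0
NC08,NTC,17000,0
NC09,NTC,18241,4
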