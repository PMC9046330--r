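component,description,unit,cost_aud
gp_consent,"GP consent: MBS item 23, level B consultation under 20 min","1 consultation",38
registration_admin,"Registration and administration: clerk time plus phone calls","30 min clerk time + calls",15
aep_consultation,"AEP pre-programme consultation: MBS item 81110","1 consultation",81
exercise_sessions,"50-week supervised group exercise, 1-h sessions, MBS item 10953","up to 10 participants per session",633
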