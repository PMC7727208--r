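expert_id,subgroup_factor,question,q025,q50,q975,usual_care_ref
A,renal_risk,uncond_less_severe,37,53,71,60
A,renal_risk,uncond_more_severe,39,56,73,60
A,renal_risk,cond_null,44,59,75,60
A,renal_risk,cond_benefit,49,64,79,60
B,renal_risk,uncond_less_severe,45,62,79,60
B,renal_risk,uncond_more_severe,47,65,82,60
B,renal_risk,cond_null,49,64,79,60
B,renal_risk,cond_benefit,53,69,83,60
C,renal_risk,uncond_less_severe,46,64,81,60
C,renal_risk,uncond_more_severe,49,67,83,60
C,renal_risk,cond_null,49,65,80,60
C,renal_risk,cond_benefit,54,70,84,60
D,renal_risk,uncond_less_severe,48,66,82,60
D,renal_risk,uncond_more_severe,51,68,85,60
D,renal_risk,cond_null,50,66,81,60
D,renal_risk,cond_benefit,55,71,85,60
E,renal_risk,uncond_less_severe,57,75,89,60
E,renal_risk,uncond_more_severe,60,77,91,60
E,renal_risk,cond_null,55,70,84,60
E,renal_risk,cond_benefit,60,75,88,60
F,renal_risk,uncond_less_severe,57,75,89,60
F,renal_risk,uncond_more_severe,60,77,91,60
F,renal_risk,cond_null,55,70,84,60
F,renal_risk,cond_benefit,60,75,88,60
G,renal_risk,uncond_less_severe,50,67,84,60
G,renal_risk,uncond_more_severe,52,70,86,60
G,renal_risk,cond_null,51,67,81,60
G,renal_risk,cond_benefit,56,72,85,60
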