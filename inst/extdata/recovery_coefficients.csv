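term,breath_count,total_inhalation,ibi
intercept,0.83,1.01,2.64
tl,0.07,0.08,0.21
bai,0.11,0.08,-0.07
bubble,-0.02,0.02,0.09
dive_duration,0.16,0.16,-0.13
tactic_forward_swimming,-0.15,-0.09,0.19
tactic_subsurface_stationary,-0.39,-0.38,-0.12
tactic_side_swim_stationary,-0.02,-0.14,-0.14
tactic_surface_tactics,-0.44,-0.51,-0.09
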