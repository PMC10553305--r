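station_id,particles_per_L
SYN01,3.65309889187222
SYN02,1.39664796091654
SYN03,0.205284011826813
SYN04,3.97270097784417
SYN05,0.205284011826813
SYN06,3.65260396665562
SYN07,0.914380179057825
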