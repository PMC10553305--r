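station_id,particles_per_L
SYN01,8.03158112582031
SYN02,7
SYN03,10.7477321797925
SYN04,13.2878035391817
SYN05,24.3810573171242
SYN06,9.23054128275203
SYN07,24.5725581695191
SYN08,17.7759271462304
SYN09,7
SYN10,16.0616750982744
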