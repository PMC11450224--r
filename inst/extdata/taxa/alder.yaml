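name: alder
genus: Alnus
heatsum_type: hourly-mean-T
delta_H: 0.10
start_day: "01-01"
T_co_C: 4.0
N_tot: 1.0e8
delta_N: 0.10
tau_s: 3600
q_low: 50
q_high: 80
P_high_mm_hr: 0.5
U_sat: 5
wind_max_scale: 1.5
injection_height_m: [1, 50]
grain_diameter_um: 22
grain_density_kg_m3: 800
window_start: "01-05"
window_end: "05-31"
cut_lat_south: null
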