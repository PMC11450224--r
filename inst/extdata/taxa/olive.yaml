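name: olive
genus: Olea
heatsum_type: daily-mean-T
delta_H: 0.10
start_day: "01-01"
T_co_C: 0.0
N_tot: 3.0e8
delta_N: 0.10
tau_s: 3600
q_low: 50
q_high: 80
P_high_mm_hr: 0.5
U_sat: 5
wind_max_scale: 1.5
injection_height_m: [2, 50]
grain_diameter_um: 28
grain_density_kg_m3: 800
window_start: "04-01"
window_end: "07-31"
cut_lat_south: null
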