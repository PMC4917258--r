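# NRAM ionic-model parameter set
T = 295
F = 96.484999999999999
Cm = 1
C_cell = 1
C_cell_phys = 20
V_cyto_pL = 0.84999999999999998
Na_o = 130
Na_i = 8
K_o = 5.4000000000000004
K_i = 140
Ca_o = 1.8
ACh = 1
G_Na = 3.3999999999999999
G_CaL = 0.031
G_CaT = 0.189
G_to = 0.002
G_Kur = 0.0080000000000000002
G_Kr = 0.35999999999999999
G_Ks = 1.3
G_f = 0.021000000000000001
G_Nab = 0.00040000000000000002
G_Cab = 0.00044299999999999998
k_Ksus_scale = 0.16
gK1_pref = 0.048925000000000003
gK1_scale = 1
g_Kleak = 0.01
g_KACh_c = 0.37487999999999999
I_NaK_max = 0.59999999999999998
Km_Nai = 10
Km_Ko = 1.5
k_NCX = 1.5500000000000001e-05
eta_NCX = 0.34999999999999998
d_NCX = 0.0001
k_tau_Na = 0.90000000000000002
V_half_m = -54
k_m = 5
V_half_h = -62.100000000000001
k_h = 4.5
k_tau_h = 2.7200000000000002
tau_h_min = 0.52000000000000002
V_tau_h = -50
V_half_y = -90
k_y = 6.3300000000000001
k_tau_Xs = 1.8999999999999999
V_max_up = 0.0011000000000000001
Km_up_f = 0.00024600000000000002
Km_up_r = 2
H_up = 1.7869999999999999
tau_tr = 2
k_leak = 1.9999999999999999e-06
k_s_rel = 4
ko_Ca = 0.068900000000000003
ko_m = 0.080000000000000002
ki_Ca = 5
ki_m = 0.00080000000000000004
K_rel_Ca = 0.00020599999999999999
n_RyR = 2
max_SR = 15
min_SR = 1
EC50_SR = 0.45000000000000001
h_SR = 2.5
TRPN_tot = 0.035000000000000003
Km_TRPN = 0.00050000000000000001
CMDN_tot = 0.11700000000000001
Km_CMDN = 0.0023800000000000002
CSQN_tot = 60
Km_CSQN = 0.80000000000000004
v_NSR = 0.081000000000000003
v_JSR = 0.0089999999999999993
K_fCa = 0.00029999999999999997
tau_fCa = 10
tau_g_min = 12
V_half_b = -37
V_half_g = -67
V_half_d = -6
V_half_f = -32
G_fb = 0.016
E_fb = -49.600000000000001
C_fb = 6.2999999999999998
G_gap = 0.5
block.I_Na = 0
block.I_CaL = 0
block.I_CaT = 0
block.I_to = 0
block.I_Ksus = 0
block.I_K1 = 0
block.I_KACh = 0
block.I_f = 0
block.I_NaK = 0
block.I_NCX = 0
block.I_Nab = 0
block.I_Cab = 0
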