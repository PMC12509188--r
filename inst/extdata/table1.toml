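# Input parameters for the axial O-PTIR signal calculation
# (transmission instrument: polystyrene bead in air, EC-QCL pump at
# 1450 cm^-1, 633 nm probe, reflective collection objective)

[probe_beam]
wavelength = 0.633        # um (VIS beam wavelength)
waist = 0.53              # um (VIS beam waist radius, omega_0p)

[pump_beam]
wavelength = 6.895        # um (IR beam wavelength at 1450 cm^-1)
waist = 5.0               # um (IR beam waist radius, omega_0h)

[pump_drive]
average_power = 6.6       # mW (avg. IR power at 1450 cm^-1)
duty_cycle = 0.025        # EC-QCL duty cycle, beta
modulation_frequency = 50 # kHz (EC-QCL modulation frequency)

[medium]
refractive_index = 1.0003    # air, n0
thermal_conductivity = 0.0262 # W/(K m), air
specific_heat = 1006          # J/(kg K), dry air at 294 K
density = 1.204               # kg/m^3, dry air at 294 K
thermo_optic = -9e-7          # 1/K, dn/dT of air at 633 nm

[absorber]
cross_section = 0.065     # um^2, expected PS absorption cross section at 1450 cm^-1
radius = 0.25             # um (bead radius)
focus_offset = 0          # um (pump-probe focus offset, delta z)

[detection]
theta_min = 21            # deg (min angle of the reflective objective)
theta_max = 30            # deg (max angle of the reflective objective)

[objectives]
raman_na = 0.55
optir_na = 0.5
optir_theta_min = 21
apodization = "sqrt_cosine"
annular_collection = true
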