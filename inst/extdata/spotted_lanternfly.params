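# Spotted lanternfly (Lycorma delicatula) species parameter file.
# Stage naming follows the four-stage modeling convention: nymphs
# (instars 1-4) = "larvae", pre-oviposition adults = "pupae",
# first-to-50%-oviposition adults = "adults".

# Lower developmental thresholds (deg C)
eggLDT = 10
larvaeLDT = 10
pupaeLDT = 10
adultLDT = 10

# Upper developmental thresholds (deg C)
eggUDT = 35
larvaeUDT = 35
pupaeUDT = 35
adultUDT = 35

# Stage durations (deg C degree-days)
eggDD = 202
larvaeDD = 890
pupDD = 630
adultDD = 146

# Phenological events (deg C degree-days, within-stage)
OWEventDD = varies
larvaeEventDD = 442
pupaeEventDD = 1
adultEventDD = 1
eggEventDD = 100

# Cold stress
coldstress_threshold = -16
coldstress_units_max1 = 300
coldstress_units_max2 = 475

# Heat stress
heatstress_threshold = 37
heatstress_units_max1 = 115
heatstress_units_max2 = 175

# Cohorts: normal distribution of degree-days to complete overwintered
# egg development
distro_mean = 190
distro_var = 15000
xdist1 = 135
xdist2 = 360
distro_shape = normal
ncohorts = 7

# Other
stgorder = OE, L, P, A, E
obligate_diapause = 1
calctype = triangle
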