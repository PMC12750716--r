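# Reconstructed a-priori mediation DAG (synthetic reconstruction: the
# source figure's exact edge set is not machine-readable, so this file
# encodes a plausible structure over the study's measured variables;
# supply your own DAG file for a different structure).
#
# Roles
exposure: x_helpful
mediator: bses_total
outcome: y_exclusive

# Exposure: perceiving nurses as always helpful. Maternal
# characteristics that shape both clinic interactions and feeding
# practice act as confounders.
hps_high -> x_helpful
education -> x_helpful
hiv -> x_helpful
employment -> x_helpful
infant_age -> x_helpful

# Mediator: breastfeeding self-efficacy (BSES-SF total)
x_helpful -> bses_total
hps_high -> bses_total
parity -> bses_total
delivery_mode -> bses_total

# Outcome: exclusive breastfeeding
x_helpful -> y_exclusive
bses_total -> y_exclusive
education -> y_exclusive
hiv -> y_exclusive
employment -> y_exclusive
infant_age -> y_exclusive

# Other structure
maternal_age -> parity

# Measured variables in the conceptual model that the rules of
# d-separation leave outside every minimal sufficient adjustment set
node: assets, hsi_high
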