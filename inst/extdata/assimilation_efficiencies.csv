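# comma-separated, dot-decimal, UTF-8
# Default assimilation efficiencies by resource type at 20 degC
# (literature-derived averages for terrestrial arthropod food webs,
#  Lang et al. 2017 Oikos; edit to suit the study system).
resource_type,e,reference_temperature_C,source
detritus,0.158,20,Lang et al. 2017
plant,0.545,20,Lang et al. 2017
animal,0.906,20,Lang et al. 2017
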