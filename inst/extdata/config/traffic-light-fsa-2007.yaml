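# UK FSA front-of-pack traffic light, previous (per-100 g) version.
# green <= green bound; red > red bound; amber in between.
# Applied to every category, cooking oils included.
model: traffic_light
version: "FSA-2007-per100g"
bands:
  total_fat:
    field: total_fat_g
    green: 3.0
    red: 17.5
  sat_fat:
    field: sat_fat_g
    green: 1.5
    red: 5.0
  sugars:
    field: total_sugars_g
    green: 5.0
    red: 22.5
  salt:
    field: salt_g
    green: 0.3
    red: 1.5
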