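# Species presets for the PMGF calculator.
# Each entry gives the five model parameters in interface units:
#   pollen_diameter  - um
#   release_height   - m
#   outcrossing_rate - percent
#   crossability     - percent
#   wind_speed       - m/s
# Values follow the published crop-to-crop case studies; users may append
# further species with the same schema.
rice:
  pollen_diameter: 40
  release_height: 0.5
  outcrossing_rate: 1
  crossability: 90
  wind_speed: 1
  source: "rice crop-to-crop case study"
wheat:
  pollen_diameter: 50
  release_height: 0.5
  outcrossing_rate: 0.5
  crossability: 90
  wind_speed: 4.5
  source: "wheat crop-to-crop case study"
maize:
  pollen_diameter: 100
  release_height: 1.5
  outcrossing_rate: 50
  crossability: 90
  wind_speed: 5
  source: "maize crop-to-crop case study"
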