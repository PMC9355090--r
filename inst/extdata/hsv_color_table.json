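{
  "version": 1,
  "encoding": "hue 0-180 (degrees halved), saturation 0-255, value 0-255; all bounds inclusive",
  "colors": [
    {"name": "black",  "hMin": [0],      "hMax": [180],     "sMin": 0,  "sMax": 255, "vMin": 0,   "vMax": 46},
    {"name": "gray",   "hMin": [0],      "hMax": [180],     "sMin": 0,  "sMax": 43,  "vMin": 46,  "vMax": 220},
    {"name": "white",  "hMin": [0],      "hMax": [180],     "sMin": 0,  "sMax": 30,  "vMin": 221, "vMax": 255},
    {"name": "red",    "hMin": [0, 156], "hMax": [10, 180], "sMin": 43, "sMax": 255, "vMin": 46,  "vMax": 255},
    {"name": "orange", "hMin": [11],     "hMax": [25],      "sMin": 43, "sMax": 255, "vMin": 46,  "vMax": 255},
    {"name": "yellow", "hMin": [26],     "hMax": [34],      "sMin": 43, "sMax": 255, "vMin": 46,  "vMax": 255},
    {"name": "green",  "hMin": [35],     "hMax": [77],      "sMin": 43, "sMax": 255, "vMin": 46,  "vMax": 255},
    {"name": "cyan",   "hMin": [78],     "hMax": [99],      "sMin": 43, "sMax": 255, "vMin": 46,  "vMax": 255},
    {"name": "blue",   "hMin": [100],    "hMax": [124],     "sMin": 43, "sMax": 255, "vMin": 46,  "vMax": 255},
    {"name": "purple", "hMin": [125],    "hMax": [155],     "sMin": 43, "sMax": 255, "vMin": 46,  "vMax": 255}
  ]
}
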