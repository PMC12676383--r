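{
  "comment": "Idealized spherical 10-20 electrode positions on the unit sphere (synthetic: computed from the standard 10-20 geometric construction, 18-degree arc steps; P3/P4 are great-circle midpoints of Pz-P7 and Pz-P8). latitude_deg is geodesic latitude from the equatorial (Fpz-T7-Oz-T8) circle toward the vertex Cz; longitude_deg is measured from the nasion, positive toward the left hemisphere.",
  "radius": 1.0,
  "sensors": [
    { "name": "O1",  "latitude_deg": 18.0,     "longitude_deg": 162.0 },
    { "name": "O2",  "latitude_deg": 18.0,     "longitude_deg": -162.0 },
    { "name": "Oz",  "latitude_deg": 18.0,     "longitude_deg": 180.0 },
    { "name": "Pz",  "latitude_deg": 54.0,     "longitude_deg": 180.0 },
    { "name": "P3",  "latitude_deg": 38.99302, "longitude_deg": 146.14130 },
    { "name": "P4",  "latitude_deg": 38.99302, "longitude_deg": -146.14130 },
    { "name": "PO7", "latitude_deg": 18.0,     "longitude_deg": 144.0 },
    { "name": "PO8", "latitude_deg": 18.0,     "longitude_deg": -144.0 }
  ]
}
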