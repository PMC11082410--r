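{
  "name": "cytosolic iron / ROS map",
  "description": "Curated factor-graph map of cytosolic iron handling and reactive oxygen species feeding the cytosolic Fenton reaction. Fifteen metabolic branches; flux balance is imposed on the cytosolic Fe2+, superoxide and hydrogen peroxide pools. Gene memberships are representative HGNC transporter/enzyme symbols per branch and are editable; the non-enzymatic Fenton module carries 20S proteasome core subunits as proxy markers of hydroxyl-radical load.",
  "metabolites": [
    "cytosolic Fe2+",
    "cytosolic Fe3+",
    "superoxide",
    "hydrogen peroxide",
    "hydroxyl radical",
    "hydroxide",
    "stored Fe3+"
  ],
  "balanced": [
    "cytosolic Fe2+",
    "cytosolic Fe3+",
    "superoxide",
    "hydrogen peroxide"
  ],
  "modules": [
    {
      "name": "Ferrous iron import",
      "genes": ["SLC11A2", "SLC39A14", "SLC39A8"],
      "consumes": [],
      "produces": ["cytosolic Fe2+"],
      "note": "Fe2+ source: divalent metal transporters"
    },
    {
      "name": "Ferric iron import and reduction",
      "genes": ["TFRC", "TF", "STEAP3", "CYBRD1"],
      "consumes": [],
      "produces": ["cytosolic Fe2+"],
      "note": "Fe2+ source: transferrin cycle and ferrireductases"
    },
    {
      "name": "Heme import and degradation",
      "genes": ["SLC48A1", "FLVCR2", "HMOX1", "HMOX2"],
      "consumes": [],
      "produces": ["cytosolic Fe2+"],
      "note": "Fe2+ source: heme uptake and heme oxygenase"
    },
    {
      "name": "Fe-S cluster synthesis",
      "genes": ["ISCU", "NFS1", "FXN", "ISCA1"],
      "consumes": ["cytosolic Fe2+"],
      "produces": [],
      "note": "Fe2+ sink: mitochondrial iron-sulfur cluster assembly"
    },
    {
      "name": "Heme synthesis",
      "genes": ["ALAS1", "ALAD", "HMBS", "FECH"],
      "consumes": ["cytosolic Fe2+"],
      "produces": [],
      "note": "Fe2+ sink: mitochondrial heme biosynthesis"
    },
    {
      "name": "Fe2+ export",
      "genes": ["SLC40A1", "HEPH", "CP"],
      "consumes": ["cytosolic Fe2+"],
      "produces": [],
      "note": "Fe2+ sink: ferroportin-mediated efflux"
    },
    {
      "name": "Fenton reaction",
      "genes": ["PSMB5", "PSMB6", "PSMB7"],
      "consumes": ["cytosolic Fe2+", "superoxide", "hydrogen peroxide"],
      "produces": ["cytosolic Fe3+", "hydroxyl radical", "hydroxide"],
      "note": "Fe2+ sink: non-enzymatic; 20S proteasome core subunits as proxy markers"
    },
    {
      "name": "Ferritin synthesis",
      "genes": ["FTH1", "FTL", "PCBP1"],
      "consumes": ["cytosolic Fe3+"],
      "produces": ["stored Fe3+"],
      "note": "Fe3+ sink: ferritin iron storage"
    },
    {
      "name": "NADPH oxidase superoxide generation",
      "genes": ["NOX1", "NOX4", "CYBA", "CYBB"],
      "consumes": [],
      "produces": ["superoxide"],
      "note": "superoxide source"
    },
    {
      "name": "Xanthine oxidase superoxide generation",
      "genes": ["XDH"],
      "consumes": [],
      "produces": ["superoxide"],
      "note": "superoxide source"
    },
    {
      "name": "Superoxide dismutation",
      "genes": ["SOD1"],
      "consumes": ["superoxide"],
      "produces": ["hydrogen peroxide"],
      "note": "superoxide sink / hydrogen peroxide source"
    },
    {
      "name": "Hydrogen peroxide import",
      "genes": ["AQP3", "AQP8"],
      "consumes": [],
      "produces": ["hydrogen peroxide"],
      "note": "hydrogen peroxide source: aquaporin channels"
    },
    {
      "name": "Catalase",
      "genes": ["CAT"],
      "consumes": ["hydrogen peroxide"],
      "produces": [],
      "note": "hydrogen peroxide sink"
    },
    {
      "name": "Glutathione peroxidase",
      "genes": ["GPX1", "GPX2", "GPX4"],
      "consumes": ["hydrogen peroxide"],
      "produces": [],
      "note": "hydrogen peroxide sink"
    },
    {
      "name": "Peroxiredoxin",
      "genes": ["PRDX1", "PRDX2", "PRDX6"],
      "consumes": ["hydrogen peroxide"],
      "produces": [],
      "note": "hydrogen peroxide sink"
    }
  ]
}
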