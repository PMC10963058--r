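[
  {"ec_number": "2.7.1.1", "organism": "Oryctolagus cuniculus", "parameter_kind": "Km", "value": 0.12, "units": "mM", "ph": 7.4, "temperature": 25, "pubmed_link": "https://pubmed.ncbi.nlm.nih.gov/0000001/"},
  {"ec_number": "2.7.1.1", "organism": "Oryctolagus cuniculus", "parameter_kind": "Km", "value": 0.05, "units": "mM", "ph": 7.0, "temperature": 30, "pubmed_link": "https://pubmed.ncbi.nlm.nih.gov/0000002/"},
  {"ec_number": "2.7.1.1", "organism": "Homo sapiens", "parameter_kind": "Km", "value": 0.08, "units": "mM", "ph": 7.4, "temperature": 37, "pubmed_link": "https://pubmed.ncbi.nlm.nih.gov/0000003/"},
  {"ec_number": "2.7.1.1", "organism": "Saccharomyces cerevisiae", "parameter_kind": "Km", "value": 0.21, "units": "mM", "ph": 6.8, "temperature": 28, "pubmed_link": "https://pubmed.ncbi.nlm.nih.gov/0000004/"},
  {"ec_number": "2.7.1.1", "organism": "Rattus norvegicus", "parameter_kind": "Km", "value": 0.3, "units": "mM", "ph": 7.2, "temperature": 37, "pubmed_link": "https://pubmed.ncbi.nlm.nih.gov/0000005/"}
]
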