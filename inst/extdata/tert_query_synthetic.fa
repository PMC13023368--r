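>tert_query_synthetic synthetic reverse-transcriptase-like query peptide (not a real TERT)
ETVFHQQMKRPTCKKTKDRMFLHHFCDRMFPFPHNRREDSVDRFFSFTDIKTQRGNHGMD
RQLKSWPLCECPQYTLDKAFTRPIHRRKLTCHMATCAVMWEVFVYVMRLRLPHTNQWVIW
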