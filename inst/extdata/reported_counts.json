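{
  "mirna_exo_total": {
    "value": 116,
    "source": "reported number of microRNAs detected in HMC-1 exosomes"
  },
  "mirna_cell_total": {
    "value": 134,
    "source": "reported number of microRNAs detected in donor HMC-1 cells"
  },
  "mirna_shared": {
    "value": 89,
    "source": "reported number of microRNAs detected in both compartments"
  },
  "mirna_exo_only": {
    "value": 27,
    "source": "reported number of microRNAs detected only in exosomes"
  },
  "mirna_cell_only": {
    "value": 45,
    "source": "reported number of microRNAs detected only in cells"
  },
  "mrna_exo_detected": {
    "value": 1849,
    "source": "reported number of mRNAs detected in exosomes"
  },
  "mrna_cell_detected": {
    "value": 12346,
    "source": "reported number of mRNAs detected in donor cells"
  },
  "mrna_detected_percent": {
    "value": 15,
    "source": "reported exosomal share of the detected cellular mRNA content"
  },
  "top10_exosome_enriched_mirnas": {
    "value": [
      "hsa-miR-451", "hsa-miR-503", "miRPlus_27560", "miRPlus_2843",
      "miRPlus_27564", "hsa-miR-583", "miRPlus_1795", "miRPlus_17890",
      "hsa-miR-663", "hsa-miR-30b"
    ],
    "source": "reported ten most exosome-enriched microRNAs, in rank order"
  }
}
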