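{
  "seed": 1,
  "files": ["synthetic_sg_lifetable.csv", "reliability_fixture.csv", "published_tables.yaml"],
  "reconstructed": {
    "synthetic_sg_lifetable.csv": "Synthetic Gompertz-Makeham life table (a = 2e-04 , b = 1.7943462e-05 , c = 1.1 ) calibrated to life expectancy at birth 83 y; stands in for an unpublished national table.",
    "external_processor_replacement": "Unit cost 5923.03 USD reconstructed by calibrating the simultaneous-vs-bimodal incremental cost to 53451 USD; not a published value.",
    "reliability_fixture.csv": "Annual points placed exactly on the published linear extrapolation S(t) = 0.998749 - 0.002911 t; the underlying manufacturer survival data are not reproduced here."
  }
}
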