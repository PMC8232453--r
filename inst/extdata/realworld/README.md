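# Real-world case-study datasets (not bundled)

The acceptance tests that reproduce published case-study numbers look for
plain-text edge lists in this directory. Place the public datasets here to
enable them:

- `fw-mangrove.tsv`, `fw-baywet.tsv`, `fw-baydry.tsv`, `fw-littlerock.tsv`
  — the four food webs as unweighted edge lists (`predator prey` or
  `src dst` per line).
- `tr-btcalpha.tsv` — the Bitcoin Alpha trust network as
  `src dst rating` per line (signed integer ratings; they are normalised
  by the maximum absolute rating at load).

Lines starting with `#` or `%` are ignored.
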