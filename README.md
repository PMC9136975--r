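# silkcode

Edible fluorescent matrix codes for on-dose medicine authentication —
encoding, synthetic imaging, CNN and classical decoding, cryptographic
hashing, and bit-error benchmarking, fully in silico.

## The problem

Anticounterfeit measures usually protect the package, not the medicine
itself. An edible taggant — a silk-fibroin film carrying an n×n matrix
code printed in three fluorescent silk inks (eCFP, eGFP, mKate2) — puts
a machine-readable key on the individual dose. Each square code unit
holds exactly one of four levels (none / cyan / green / red), so one
physical code is photographed as three binary images through three
excitation–emission filter sets.

`silkcode` implements the digital pipeline around such codes:

* **Key model.** Each channel image yields a binary channel key `K_b`
  of n² bits (bit *i* = 1 iff cell *i*, row-major, carries that ink).
  The three keys concatenate as `K_b1 + K_b2 + K_b3` into a digitized
  key of 3n² bits — 147 bits for a 7×7 code (75 and 243 for 5×5 and
  9×9). Encoding capacity is c^s (c = bit-level, s = key size):
  2¹⁴⁷ ≈ 1.78×10⁴⁴ nominal for 7×7, computed with exact
  arbitrary-precision integers. Quaternary and double-binary
  reconstructions of the key are included.
* **Synthetic imaging.** A seeded generator reproduces the unit-patch
  augmentation scheme: libraries of filled/empty square units
  (101×101 px at full scale) with edge roughness, intensity
  inhomogeneity, blur, and background noise, tiled into code canvases
  (692×648 px full scale, 96×96 desk scale) with placement jitter, and
  an intensity-degradation hook for photobleaching studies.
* **Decoders.** A 2D CNN (three conv layers with batch norm, ReLU and
  overlapping max-pooling, a 400-node FC layer, linear n²-bit output;
  MSE loss, ADAM, mini-batch 100, ≤15 epochs) trained on synthetic
  images, plus a classical grid-threshold reader used as a
  deterministic oracle and fallback.
* **Authentication.** Digitized keys are serialized, hashed (MD5 →
  128-bit hashed key; SHA-256/SHA-512 recommended) and checked against
  a JSON registry of product records by exact digest match.
* **Benchmarks.** Bit error ratio (BER) evaluation over large labelled
  sets and paired-seed intensity-degradation sweeps.

See `vignettes/silkcode-methods.Rmd` for the full model description,
parameter meanings, and design choices.

## Worked example

```r
library(silkcode)

# a random 7x7 code and its keys
code <- random_code(7, seed = 1)
keys <- encode_channels(code)          # three 49-bit channel keys
key  <- concat_key(keys)               # 147-bit digitized key
print(key)
#> digitized_key: 147 bits (n = 7; order ECFP,EGFP,MKATE2)
#> 0000000011010001101000010110101001100010100000010010100100000001000010
#> 01000000100000001000010001000000000100001100000010000001000000000001010000000

format(capacity(2, 147))               # exact nominal key space
#> "178405961588244985132285746181186892047843328"
bigint_scientific(capacity(2, 147))
#> "1.78e+44"

# render the three fluorescence images and read them back
cfg <- imaging_config("desk")          # 96x96 miniature geometry
lib <- build_patch_library(200, cfg, seed = 2)
imgs <- render_code(code, lib, cfg, seed = 3)
decoded <- baseline_decode_set(imgs, grid_layout(cfg))
identical(decoded$bits, key$bits)
#> TRUE

# hash and authenticate
h <- hash_key(decoded, "sha256")
print(h)
#> SHA256 hashed key (256 bits):
#> 8bf1e851f833c9fafbc0f258211193a6751fb910abc0005b947ea26fb6b45605
reg <- register_key(key_registry("sha256"), h,
                    list(product = "pediatric syrup", dosage = "5 mg",
                         expiry = "2027-06-01"))
verify_key(reg, decoded)$authentic
#> TRUE
```

Training the CNN decoder end-to-end on generated data:

```r
res <- run_ber_benchmark(train_n = 5000, eval_n = 5000,
                         imaging = imaging_config("desk"),
                         cnn = cnn_config("desk"), seed = 1)
res$report
```

A command-line interface wrapping these functions is installed at
`inst/cli/silkcode` (`generate`, `train`, `decode`, `hash`, `register`,
`verify`, `benchmark`, `sweep`).

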