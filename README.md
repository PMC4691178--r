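# subnucfuse

Prediction of protein **sub-nuclear localization** — the compartment of
the nucleus (nucleolus, chromatin, nuclear speckle, nuclear pore complex,
...) a nuclear protein resides in — from fixed-length sequence
representations. The package is aimed at computational biologists who
have protein sequences (FASTA), optionally per-protein position-specific
scoring matrices (PSSMs) from an iterative profile search, and a label
table, and want a reproducible encode → fuse → reduce → classify →
evaluate pipeline, plus a synthetic-data generator that makes every stage
testable without any external database.

## The method

Three single representations of a protein of length *L*:

* **DipC** (420D): residue frequencies `aa_i / L` (20) plus ordered
  dipeptide frequencies `cr_i / (L − 1)` (400), residues indexed
  alphabetically;
* **PseAAC** (20 + 2λ D, default λ = 10 → 40D): composition plus λ tiers
  of hydrophobicity/hydrophilicity sequence-order correlation factors
  `τ_{2k−1} = mean_i h1(R_i) h1(R_{i+k})` (and likewise `h2`), all
  normalized by the shared denominator `Σf + w Στ`;
* **compressed PSSM** (210D): from the `L × 20` score matrix `P`, the
  length-free symmetric matrix `M = PᵀP` (20 × 20 = 400 entries) kept as
  its 210 lower-triangle elements.

Two fused representations combine a composition block *A* with the PSSM
block *B* through per-class **balance factors** `r_i ∈ (0, 1)`:

```
V_i = [ r_i · A_i , (1 − r_i) · B_i ]        i = 1..n locations
```

giving **DipPSSM** (630D) or **PseAAPSSM** (250D). The balance vector
`R = (r_1, ..., r_n)` is optimized by a greedy-initialized real-coded
genetic algorithm: 50 restarts of a per-coordinate 0.01-grid scan
starting from all-0.5 seed the GA population, and selection / arithmetic
crossover / Gaussian mutation / elitist replacement minimize the fitness
error (1 − cross-validated overall success rate). **LDA** solves
`S_B w = λ S_W w` (ridge-regularized when `S_W` is singular) to project
onto at most C − 1 discriminant components, and a **cosine-similarity
KNN** classifies, with k chosen from 1..10. Stratified K-fold
cross-validation (repeated, averaged) and the jackknife report per-class
sensitivity, specificity, accuracy, Matthews correlation coefficient, and
the overall success rate `Σ T(i) / Σ N(i)`.

## Worked example

Everything below is computed from generated data, so it runs offline and
reproduces exactly.

```r
library(subnucfuse)

ds <- generate_synthetic(n_classes = 3, per_class = 15,
                         length_range = c(20, 40), pssm_profile_shift = 1.5,
                         pssm_noise_sd = 3, seed = 1)
A <- encode_all(ds, "dipc")    # 45 x 420
B <- encode_all(ds, "pssm")    # 45 x 210

res <- optimize_balance(A, B, ds$labels,
                        search_config(init_restarts = 2, generations = 10,
                                      seed = 1),
                        mode = "candidate-class")
cat("fitness error:", round(res$best_fitness, 4), "\n")
cat("R:", sprintf("%.2f", as.numeric(res$best_R)), "\n")
#> fitness error: 0.0667
#> R: 0.00 0.00 0.00

report <- cross_validate(list(A = A, B = B), ds$labels,
                         R = as.numeric(res$best_R),
                         K = 5, repeats = 5, lda_dim = "max", seed = 7)
cat("best k:", report$best_k, "\n")
print(report$metrics)
#> best k: 1
#> Per-class metrics (45 samples):
#>  class   TP   TN  FP  FN     SE     SP    ACC    MCC
#>      1 14.6 29.6 0.4 0.4 0.9733 0.9867 0.9822 0.9611
#>      2 14.8 29.8 0.2 0.2 0.9867 0.9933 0.9911 0.9805
#>      3 14.6 29.6 0.4 0.4 0.9733 0.9867 0.9822 0.9605
#> Overall success rate: 0.9778
```

Reading the output: the optimizer's fitness error of 0.0667 means its
internal 3-fold CV misclassified 6.7% of proteins at the best balance
vector it found. All three factors sit at the lower clamp (printed 0.00):
on raw scales the `PᵀP` magnitudes dwarf the frequency blocks, so when
class signal is present in the PSSM block the search drives the factors
toward it — see the vignette for when and why to pass
`standardize = TRUE`. The per-class table averages one-vs-rest confusion
counts over the 5 CV repeats (hence fractional counts); an MCC near 1
means near-perfect discrimination of that location, and 97.8% of all
proteins were assigned their true compartment.

Command-line equivalents:

```sh
Rscript inst/cli/subnucfuse.R simulate --classes 3 --per-class 15 --seed 1 --out fx/
Rscript inst/cli/subnucfuse.R encode   --fixture fx --representation dipc --out dipc.tsv
Rscript inst/cli/subnucfuse.R optimize --fixture fx --representation dippssm --out opt/
Rscript inst/cli/subnucfuse.R evaluate --fixture fx --representation dippssm \
        --balance opt/balance.tsv --lda max --out metrics/
```

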