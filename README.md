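# swapfold

Coarse-grained simulation and prediction of **domain-swapped misfolding** in
tandem multidomain proteins.

Proteins made of tandem repeats of one domain (titin's Ig domains,
fibronectin repeats, polyubiquitin, ...) can misfold into long-lived
domain-swapped states: two native-*like* folds assembled from exchanged
halves of adjacent repeats.  The "central domain" of such a misfold is a
circular permutant of the native fold — the chain cut at a loop position K
with the original termini joined.  swapfold provides, in one package, the
apparatus to study which folds are prone to this and why:

* **Structures** — C-alpha reduction of PDB chains, plus a synthetic
  beta-meander generator with controllable termini separation, so every
  module is testable without downloads.
* **Gō models** — one-bead structure-based energy functions with
  Miyazawa–Jernigan-style well depths; tandem dimer models in which every
  native contact (i, j) is duplicated four ways,
  E(i,j) = E(i+L,j) = E(i,j+L) = E(i+L,j+L), so swapped misfolds are exactly
  as native-like as the native fold; Gly-Ser linker handling.
* **Permutant algebra** — frame-shifted contact sets S_in/S_out for every
  cut K, the logistic contact fractions Q_K (beta = 50 nm^-1, lambda = 1.2),
  relative contact order RCO_K, the nucleus-position coordinate ij-bar, and
  loop-based cut-site enumeration.
* **Sampling** — compiled BAOAB Langevin dynamics (friction 0.1 ps^-1,
  10 fs steps), first-passage misfolding campaigns with per-K
  classification, umbrella sampling along Q with WHAM unbiasing, and
  free-energy analysis: stability dG_s = kT ln(Z_fold/Z_unf), barrier
  dG_f = F(Q_barrier) − F(Q_unfolded), and working-temperature selection
  (barrier near 2.5 kT).
* **WSME Ising model** — single-sequence Wako–Saitô–Muñoz–Eaton model of
  first-domain formation on the duplicated contact map with a midpoint
  strain penalty Ep; exact enumeration and a detailed-balanced Metropolis
  sampler, with F(Q_res, ij-bar) surfaces.
* **Alchemical predictor** — circular-permutant destabilization
  ddG_tot = dG_J (join the termini, peeling at most nine residues per
  terminus under the geometric condition d < (n_peel − M) r0, r0 = 3.5 A,
  M ∈ {0, 6}) + dG_C (cut the loop at K), with the entropy per residue
  ds = sum(eps)/(T N).
* **Statistics** — mid-rank Spearman correlations, binomial population
  errors, and a packaged reference table of misfolding statistics for seven
  tandem-repeat proteins (SH3, PDZ, TNfn3, UBQ, SH2, Titin I27, GB1).

## Worked example

```r
library(swapfold)

toy    <- make_toy_structure(toy_spec(n_strands = 4, strand_length = 5,
                                      loop_length = 5, termini_gap = 0.5,
                                      seed = 1))
model  <- build_go_model(toy)
tandem <- build_tandem_model(model, "GS")

enumerate_cut_sites(model)
#> # A tibble: 3 x 3
#>       K loop_start loop_end
#>   <int>      <dbl>    <int>
#> 1     8          7        9
#> 2    18         17       19
#> 3    28         27       29

alc <- ddg_total(toy, model$contacts, K = c(8, 18, 28),
                 temperature = 560, M = 0)
as.data.frame(round(alc[, c("K", "dG_J", "dG_C", "ddG_tot")], 3))
#>    K  dG_J   dG_C ddG_tot
#> 1  8 6.465 -6.294   0.171
#> 2 18 6.465 -5.420   1.045
#> 3 28 6.465 -5.801   0.663
```

Each row predicts how much less stable the circular permutant cut after K
is than the wild type: the join step peels two contact-bearing terminal
residues of this nearly closed barrel (6.5 kcal/mol of broken contacts
net of the entropy they gain), the cut step unfolds a few loop residues
whose entropy outweighs their weak contacts, and the small net `ddG_tot`
says this fold tolerates circular permutation — its permutants, and hence
its domain-swapped misfolds, are almost as stable as the native fold.
Reference rank correlations between permutant stability and misfolding
populations:

```r
correlation_report(misfolding_reference())
#> # A tibble: 7 x 5
#>   protein   n_states rho_rco rho_dGf rho_dGs
#>   <chr>        <int>   <dbl>   <dbl>   <dbl>
#> 1 GB1              5   0      -0.707   0.707
#> 2 PDZ              6   0.319  -0.870   0.941
#> 3 SH2              8  -0.497   0.102   0.814
#> 4 SH3              4  -0.632  -0.316   0.632
#> 5 TNfn3            7   0.342  -0.108   0.739
#> 6 Titin_I27        7  -0.459  -0.926   0.857
#> 7 UBQ              5   0.559  -0.707   0.707
```

The `rho_dGs` column is the headline result: across proteins, the final
population of each fold (native or misfolded) tracks the stability of the
corresponding isolated domain, with rank correlations 0.63–0.94 for the
misfolding-prone folds.

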