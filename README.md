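# decaaf

Automated selection of directed-evolution starting points by active-site
congruence. Given a template enzyme whose catalytic motif is known, `decaaf`
searches candidate protein structures for constellations of reactive side-chain
atoms that are spatially and electrostatically congruent with the template
motif (or with any partial sub-motif of it), ranks the candidates, superposes
the best match onto the template in an exact canonical frame, audits the steric
surroundings of the matched site, and proposes the mutations that would
complete the motif.

## The scientific problem

Engineering a new catalytic activity is far easier when the starting protein
already contains most of the required active site. For a motif of *k* reactive
atoms \(x_1,\dots,x_k\) the package compares, between template and target, two
rigid-motion invariants:

* the pairwise distances \(d_{ij} = \lVert x_i - x_j \rVert\) (Å), and
* the pairwise electrostatic potential differences
  \(\mathrm{PD}_{ij} = V(x_i) - V(x_j)\) (kT/e), from a Poisson–Boltzmann grid
  (OpenDX), a per-atom table, or a built-in screened-Coulomb fallback.

A candidate assignment scores

\[ S = \frac{1}{\binom{k}{2}} \sum_{\text{pairs } p} \left[
   w_d \frac{|\Delta d_p|}{d^{\mathrm{ref}}_p} +
   w_v \frac{|\Delta \mathrm{PD}_p|}{\max(|\mathrm{PD}^{\mathrm{ref}}_p|, V_{\min})}
   \right], \]

lower is better, zero iff perfectly congruent. A whole target is summarised by
the **DScore** — the mean best score over a library of partial motifs, with a
fixed penalty for partial motifs left unmatched — and targets are ranked
ascending. Matched sites are superposed by an exact three-anchor map sending
anchor *a* to the origin, *b* to the +X axis and *c* into the Z = 0 plane
(proper rotation, so chirality is preserved). See the methods vignette
(`vignettes/methods.Rmd`) for derivations, parameter semantics, and the
synthetic generator's realism limits.

## Worked example

The classic positive control: the Ser195–His57–Ser214 scaffold of human
neutrophil elastase (PDB 1B0F) against phospholipase A2 activator p14a
(PDB 1CFE), whose Ser49–His48–Tyr36 site is a latent esterase triad.

```r
library(decaaf)

hne <- anchor_fixture("hne_1b0f")    # Ser195, His57, Ser214 reactive atoms
cfe <- anchor_fixture("p14a_1cfe")   # Ser49,  His48,  Tyr36

# allow Tyr at the third position, then search the target
m  <- expand_equivalence(
        build_template(hne, data.frame(resno = c(195, 57, 214))),
        "Ser214", "TYR")
best <- find_matches(m, cfe)[[1]]
best$assignment$residue
#> [1] "Ser49" "His48" "Tyr36"
round(best$dev_d, 1)   # reference-minus-target pairwise deviations (Å)
#>   ab   ac   bc
#>  0.1  0.0 -0.2

# superpose both sites into the common canonical frame
sp <- run_superpose(hne, data.frame(resno = c(195, 57, 214)),
                    cfe, data.frame(resno = c(49, 48, 36)))
sp$summary
#>   structure anchor     label before_x before_y before_z  after_x  after_y
#> 1       hne      1 Ser195/OG     64.4     57.0     53.8 0.000000 0.000000
#> 2       hne      2 His57/ND1     63.3     54.8     58.2 5.040833 0.000000
#> 3       hne      3 Ser214/OG     63.6     50.6     56.1 4.975368 4.704861
#> 4       cfe      1  Ser49/OG      8.8     -6.3     -4.8 0.000000 0.000000
#> 5       cfe      2 His48/ND1      9.2     -2.4     -1.8 4.936598 0.000000
#> 6       cfe      3  Tyr36/OH     13.7     -1.6     -3.7 4.778594 4.947225
#>         after_z  residual
#> 1  0.000000e+00 0.0000000
#> 2 -1.421085e-14 0.1042352
#> 3  0.000000e+00 0.3121862
#> 4  0.000000e+00 0.0000000
#> 5  0.000000e+00 0.1042352
#> 6  8.881784e-16 0.3121862
```

Anchor-by-anchor the two sites coincide to 0.1–0.3 Å. Ranking the target
against synthetic decoy structures puts it first:

```r
tgt_dir <- "..."   # directory of candidate .pdb files
run_scan(hne, data.frame(resno = c(195, 57, 214),
                         allowed = c("", "", "TYR")),
         tgt_dir, k = 3)
#>       id description     dscore
#> 1    cfe             0.02569822
#> 2 synthA             0.07837879
#> 3 synthB             0.18349238
```

A shell front end wraps the same runs
(`Rscript inst/cli/decaaf.R scan|superpose|neighbors|suggest|fixtures ...`);
every subcommand exits non-zero on error.

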