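# sigreverse

Drug-repurposing screens built on the signature-reversal principle: if a
disease shifts a tissue's transcriptome in one direction, a compound that
shifts expression the opposite way is a therapeutic candidate. `sigreverse`
implements the complete workflow for querying a Connectivity-Map-style
database of rank-transformed drug perturbation profiles with a disease
expression signature, as used in transcriptome-driven drug discovery for
complex diseases such as diabetic nephropathy (where the disease signature
contrasts late-stage against early-stage glomerular expression).

It is aimed at computational biologists who have (a) a normalized log2
expression matrix with sample groups and (b) a rank database — one full
probe ranking per drug treatment instance, rank 1 = most up-regulated —
plus a probe-to-gene lookup table.

## The two scoring algorithms

**KS connectivity score.** A query signature is a pair of disjoint tag
lists (up/down probes, here the 1000 largest-changing probes by moderated
t). For a tag list with sorted positions `V(1..t)` in a ranking of `n`
probes, the enrichment statistic is

    a = max_j [ j/t − V(j)/n ],   b = max_j [ V(j)/n − (j−1)/t ]
    ks = a  if a > b,  else  −b

The raw instance score is `s = ks_up − ks_down`, set to 0 when both tag
lists fall at the same end, and normalized across instances so the extremes
attain ±1: positive scores are divided by `max(s)`, negative by `|min(s)|`.
A strongly *negative* connectivity score marks a compound that reverses the
query state.

**Set-overlap reversing score.** Probe ranks are condensed to gene ranks
(median over a gene's probes), each instance's drug signature is the
top/bottom 500 genes of that condensed order (`up_di` / `down_di`), and the
disease DEG sets (`up` / `down`, FDR < 0.05 and fold change > 1.5) are
scored by

    Score_di = |up ∩ down_di| + |down ∩ up_di| − |up ∩ up_di| − |down ∩ down_di|

i.e. reversed minus aggravated genes. The pipeline combines both screens:
the consensus is the set of perturbagen names in the top-m of both
rankings. Downstream, candidate drugs are clustered by Jaccard similarity
of their reversed gene sets (average linkage) and reversed genes are tested
for gene-set over-representation with Fisher's exact test.

## Worked example

The package ships the printed top-20 result tables of a published
diabetic-nephropathy glomerular screen as plain-text fixtures. Recomputing
the connectivity normalization from the raw per-instance up/down scores:

```r
library(sigreverse)
tab <- readr::read_tsv(sigreverse_example("dn_ks_top20.tsv"),
                       show_col_types = FALSE)
conn <- normalize_connectivity(combine_scores(tab$up, tab$down))
head(data.frame(perturbagen = tab$perturbagen, connectivity = round(conn, 3)), 5)
#>       perturbagen connectivity
#> 1         Bepridil       -1.000
#> 2           MG-262       -0.960
#> 3 Alcuronium chloride    -0.953
#> 4         Prazosin       -0.953
#> 5   Piperlongumine       -0.943
```

Bepridil's raw score `−0.077 − 0.223 = −0.300` is the most negative of the
twenty, so it normalizes to exactly −1; every other negative score is
divided by 0.300. A full synthetic end-to-end run with planted ground truth:

```r
genes <- sprintf("g%05d", 1:3500)
dsig  <- signature_set(genes[1:100], genes[101:150], space = "gene")
simdb <- simulate_rank_database(5000, 200, disease_signature = dsig,
                                n_reversers = 5, strength = 0.2, seed = 42)
up_p   <- simdb$map$probe_id[simdb$map$gene_symbol %in% dsig$up]
down_p <- simdb$map$probe_id[simdb$map$gene_symbol %in% dsig$down]
sime <- simulate_expression(5000, effect_log2 = 2, sd = 0.5, seed = 43,
                            feature_ids = simdb$map$probe_id,
                            planted_up = up_p, planted_down = down_p)
res <- run_pipeline(pipeline_config(expression = sime$expr,
                                    rank_meta = simdb$db,
                                    probe_map = simdb$map,
                                    consensus_m = 5, seed = 1))
res$consensus$perturbagen
#> [1] "reverser_drug_03" "reverser_drug_02" "reverser_drug_05"
#> [4] "reverser_drug_01" "reverser_drug_04"
```

All five planted reversers top both screens and form the consensus exactly.
Result objects are tibbles (`tidy()`, `glance()`) with `autoplot()` methods
(volcano, connectivity lollipop, reversal heat map, enrichment dots).

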