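# mirnetscreen

Network-based screening of microRNA biomarkers from miRNA–mRNA
regulatory networks, for computational biologists studying diseases —
such as hepatocellular carcinoma — where cohort heterogeneity defeats
plain differential expression.

Most network methods rank miRNAs by how connected they are. This package
ranks them by how *irreplaceable* they are. For each miRNA *i* in a
condition-specific network it computes two vulnerability indices:

- **NOD(i)** — the number of *i*'s in-network targets with gene
  in-degree 1, i.e. genes regulated *exclusively* by *i*;
- **TFP(i)** — |targets(i) ∩ TF| / |targets(i)|, the transcription-factor
  fraction of *i*'s targets.

Significance of both indices is assessed against a degree-preserving
rewiring null: `n_null` replicates of the bipartite network randomized by
edge swaps that preserve every node's degree, with the one-sided add-one
p-value *p* = (1 + #{null ≥ observed}) / (`n_null` + 1). A miRNA is a
candidate biomarker when NOD and TFP are both significant (*p* < α) in
both the miRNA-seeded and the gene-seeded condition network.

Around this core the package implements the full screening pipeline:

- reference-network assembly from validated + predicted interaction
  evidence under per-tool score filters and ≥2-of-3 tool agreement;
- differential-expression screening — Welch t for miRNAs; six statistics
  (t, COPA, OS, ORT, MOST, LSOSS) for genes, with the method chosen by
  cross-dataset overlap of the top-40% lists, plus k-NN imputation;
- classifier evaluation of 1–2-marker panels (stratified fivefold-CV SVM,
  rank AUC, sensitivity/specificity/accuracy);
- clinical association for tissue-microarray data (weighted ISH/IHC
  scoring, Pearson χ² without continuity correction, Mann–Whitney U,
  Kaplan–Meier / log-rank);
- a seeded synthetic-data generator with planted ground truth so the
  entire pipeline is testable end to end with no downloads.

## Worked example

Screen a small synthetic study end to end (5 planted biomarkers among 60
miRNAs, 10 exclusive targets each):

```r
library(mirnetscreen)

cfg  <- synth_config(seed = 11, n_mirnas = 60, n_genes = 300,
                     n_planted = 5, planted_exclusive_targets = 10,
                     n_de_mirnas = 20, n_samples_per_group = 10)
net  <- generate_network_evidence(cfg)
expr <- generate_expression(cfg, net$truth)
res  <- run_biomarker_screen(net$evidence, net$tf_list,
                             expr$mirna, expr$mrna,
                             n_null = 499, seed = 3)

res$reference
#> regulatory_network: 60 miRNAs, 295 genes, 860 edges
res$de_method
#> [1] "LSOSS"
res$candidates[, c("mirna_id","nod1","tfp1","nod2","tfp2","direction")]
#>   mirna_id nod1 tfp1 nod2  tfp2 direction
#> 1  miR-001   10  0.6    8 0.750        up
#> 2  miR-003   10  0.5    9 0.444        up
#> 3  miR-004   10  0.4   10 0.400      down
#> 4  miR-005   10  0.4   10 0.400        up
```

Four of the five planted miRNAs are recovered with no false positives:
each candidate's NOD equals (nearly) its planted exclusive-target count
in both condition networks, its TFP sits far above the 0.1 background TF
rate, and all four p-values (not shown) are below 0.05. The gene
statistic was chosen automatically as the most cross-study-consistent of
the six.

Clinical stage, from printed 2×2 counts (tumour size ≤5 / >5 cm versus
high/low marker expression):

```r
ct <- chi2_association(matrix(c(16, 19, 13, 42), 2))
sprintf("chi2 = %.3f, p = %.4f", ct$chi2, ct$p_value)
#> [1] "chi2 = 4.774, p = 0.0289"
```

i.e. low marker expression is associated with larger tumours at p < 0.05.

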