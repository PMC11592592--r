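# mirdiva

Interpretable structural descriptions of precursor microRNA from a
disentangled variational autoencoder and a latent-space decision tree.

## The problem

Pre-miRNAs are hairpin-folded RNA intermediates whose computational
detection is usually done by black-box classifiers. This package
implements a description-generation framework: instead of only scoring
a molecule, it learns *which structural properties* characterize the
pre-miRNA class and reports them as readable rules such as

```
stem_length>28=1 AND pair_fraction>0.766667=1 AND max_bulge_size>3=0 => pre-miRNA  [n=356, purity=1.00]
```

## The method

1. **Structured encoding.** A record (RNA sequence + Vienna dot-bracket
   stem-loop) is drawn as a 100x25 bar image with 5 one-hot color
   channels (A/C/G/U/gap): 5' arm along the top edge, 3' arm along the
   bottom, paired bases sharing a column, gaps as 2-px black bars, bar
   length encoding bond strength (strong Watson-Crick bonds 3 px, weak
   bonds 4-12 px growing with consecutive weak runs). A length-100
   binary bond vector *m* marks strong-bond columns. The codec is
   exactly invertible (`encode_image()` / `decode_image()`).
2. **Disentangled representation.** A DIVA-style VAE with three latent
   spaces — z_m (shape/bond strength, conditional prior on *m*), z_y
   (class, conditional prior on the label), z_x (remaining variance,
   standard normal) — each with its own encoder and inverse
   autoregressive flow, plus auxiliary classifiers (y|z_y, y|z_m,
   m|z_m). The objective is the three-KL ELBO

   L = E[log p(x|z_m,z_y,z_x)] − β_m KL(q(z_m|x) ‖ p(z_m|m))
       − β_x KL(q(z_x|x) ‖ p(z_x)) − β_y KL(q(z_y|x) ‖ p(z_y|y))

   augmented as F = L + α_y1 log q(y|z_y) + α_y2 log q(y|z_m)
   + α_m log q(m|z_m), with β = 0.5, α_y = 12, α_m = 1, trained by Adam
   (lr 5e-4, batch 64). The decoder factorizes each bar into a
   categorical height (vocabulary {0,2,...,12}) times a categorical
   color. The neural core runs on a small reverse-mode autodiff engine
   written in R; gradients are verified against finite differences.
3. **Description tree.** Structural features (pair fraction, lengths,
   bulge statistics, loop geometry) are binarized at data-driven
   thresholds; a decision tree over z_m picks, at each node, the
   feature whose linear-SVM predictor (accuracy gate 0.8) yields the
   highest information gain on the class (max depth 5, min node 10).
   Root-to-positive-leaf paths are the learned pre-miRNA description.

A synthetic hairpin generator with planted structural parameters makes
the whole pipeline testable end to end, including a planted-rule regime
where the true class is a known conjunction
(`pair_fraction > 0.7 AND total_length > 60 AND max_asymmetric_bulge < 5`)
that the tree is expected to rediscover.

## Worked example

```r
library(mirdiva)

# a balanced synthetic benchmark: 500 hairpins and decoys
records <- generate_dataset(generator_config(n_samples = 500, seed = 5))
records[[1]]
#> <structured_rna> pos00001|mech=hairpin|stem=19|loop=13|pf=1.000000000000|nb=0|mb=0|asym=0 (51 nt, label=1)
#> CAGGUAGGCGUCCCAUCUCACGAGCUAUACGAGAGAUGGGACGCCUACCUG
#> (((((((((((((((((((.............)))))))))))))))))))

# exact image codec
enc <- encode_image(records[[1]])
dim(enc$image)   #> [1] 100  25   5
sum(enc$m)       #> [1] 19        (strong-bond columns)
identical(decode_image(enc$image)$sequence, records[[1]]$sequence)  #> TRUE

# train the desk-scale DIVA model (a couple of minutes on one CPU)
tensors <- dataset_tensors(records)
model <- diva_train(tensors, diva_config("desk", epochs = 15), seed = 7)
tail(model$history$loss, 1)   #> 351.8768   (minimized -F, per-record)

# class information lives in z_m and z_y, not z_x
z <- diva_encode(model, tensors)
linear_probe_accuracy(z$z_m, tensors$y)  #> 1
linear_probe_accuracy(z$z_y, tensors$y)  #> 1
linear_probe_accuracy(z$z_x, tensors$y)  #> 0.76

# descriptions from the latent decision tree
ft <- feature_table(records)
fb <- binarize_features(ft, default_thresholds(ft))
tree <- fit_latent_tree(z$z_m, tensors$y, fb, tree_config())
cat(format_descriptions(extract_descriptions(tree)), sep = "\n")
#> pair_fraction>0.702963=1 AND max_asymmetric_bulge>1=1 AND n_bulges>8=0 AND stem_length>19=1 => pre-miRNA  [n=226, purity=1.00]
#> pair_fraction>0.702963=1 AND max_asymmetric_bulge>1=1 AND n_bulges>8=0 AND stem_length>19=0 AND loop_length>4=1 => pre-miRNA  [n=19, purity=1.00]
#> pair_fraction>0.702963=1 AND max_asymmetric_bulge>1=1 AND n_bulges>8=1 AND loop_length>5=1 => pre-miRNA  [n=5, purity=1.00]
```

The probe accuracies read: a linear classifier recovers the class
perfectly from the shape and class latent spaces but performs far worse
on the residual space — the intended disentanglement. The printed
descriptions are conjunctions of structural conditions ending in
pre-miRNA leaves, with leaf support and purity.

The same flow, end to end with artifacts and a reproducibility
manifest:

```r
run_pipeline(pipeline_config(out_dir = "run", seed = 3, n = 1000,
                             dataset = "planted", epochs = 60))
```

A thin CLI over these functions is installed at
`system.file("cli", "mirdiva", package = "mirdiva")` with subcommands
`simulate / encode / train / tree / describe / evaluate / run`.

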