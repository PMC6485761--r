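# mmcnn: multi-modal multi-sized-filter CNNs for RBP binding-site prediction

RNA-binding proteins (RBPs) recognize their target sites through sequence
preferences, secondary-structure preferences, or both. CLIP-seq experiments
produce large sets of bound (positive) and unbound (negative) RNA fragments,
and the computational task is twofold: predict whether a new sequence is
bound, and explain the prediction by extracting the sequence and structure
motifs the model has learned. `mmcnn` implements a bimodal deep
convolutional network (the mmCNN architecture) and its companion
motif-extraction procedure, *response enrichment*, for exactly this task.

The package is aimed at computational biologists who work with CLIP-seq
style data: sequences trimmed to a 200-nt window around the putative binding
site, plus suboptimal secondary-structure ensembles from a folding tool such
as RNAshapes (dot-bracket strings ranked by free energy). It also ships a
synthetic planted-motif generator with full ground truth, so every stage —
encoding, training, prediction, motif extraction — can be exercised and
tested without any external download.

## The model

**Structure feature.** For each sequence, the free energies `e_l` of its
suboptimal structures are converted into Boltzmann weights

    p_l = exp(-e_l / kT) / sum_m exp(-e_m / kT)

with `k = 0.001987 kcal mol^-1 K^-1` and `T = 310.15 K`, keeping the 100
lowest-energy structures. The *stem-pair probability matrix* is then

    p(i, j) = sum_l p_l * [ residues i and j are paired in structure l ]

a symmetric 200 x 200 matrix whose entry is the ensemble probability that
residues i and j form a stem pair. This, together with the 200 x 4 one-hot
sequence, is the network's bimodal input.

**Architecture.** Every layer is a *multi-sized convolution module* (MCM):
parallel convolutions with filter lengths 8, 16 and 32 (so that short,
medium and long motifs are all detectable), ReLU, max pooling, and stacking
of the per-size outputs. A sequence MCM (filters `f x 4`, 16 filters per
size) and a structure MCM (filters `f x f`, reduced over the pairing-partner
axis) feed a stacked 200 x 6 x 16 combined representation; three further
combined MCMs (32 filters per size, halving the position axis each:
200 → 100 → 50 → 25) feed a 64-unit dense layer and a sigmoid output trained
with binary cross-entropy (Adadelta, learning rate 1.0, rho 0.95). Training
uses stratified 10-fold cross validation; the ensemble score is the
arithmetic mean of the ten fold scores.

**Response enrichment.** For each positive sample the position `x_n` and
filter `k_n` of the maximal combined response are located; windows of the
combined representation are multiplied elementwise by the responding
filter's weights and summed over samples. The best filter size and the best
sequence/structure filter types are selected by response score, shifting
constants `d_t` re-anchor the windows, and the per-sample mapping
`P(x_n, d_t) = 2(x_n + d_t)` pulls the analysis back to raw coordinates.
The summed sequence enrichment becomes a PWM by a position-wise softmax
(exported in MEME minimal format); the structure enrichment becomes a 1-D
stem-score profile; aligning both via `d_seq - d_struct` yields the combined
motif.

## Worked example

```r
library(mmcnn)

# simulate a small labeled dataset: an 8-mer planted in the 5' arm of a
# hairpin whose ensemble carries 90% of the Boltzmann mass on the stem
spec <- synthetic_spec(n_pos = 400, n_neg = 400, motif = "UGUAAAUA",
                       motif_positions = c(95, 95),
                       stem = list(start = 95, length = 6, loop = 4, target = 0.9),
                       seed = 42)
sim <- generate_dataset(spec, "rbp_demo")

# read the files back through the standard readers and encode
pos <- read_labeled_fasta("rbp_demo/positives.fa", label = 1)
neg <- read_labeled_fasta("rbp_demo/negatives.fa", label = 0)
ens <- parse_ensemble_file("rbp_demo/ensembles.txt")
data <- encode_dataset(rbind(pos, neg), ens)

cfg <- mmcnn_config(filter_sizes = c(4, 8, 16), filters_per_size = 8,
                    combined_filters = 8, epochs = 10)
fit <- mmcnn(data, cfg, folds = 2, seed = 1)
print(fit)
#> Bimodal multi-sized-filter CNN (mmCNN)
#>   input: 200 nt window; sequence (200 x 4) + structure (200 x 200)
#>   filter sizes: 4, 8, 16; 8 first-layer + 8 combined filters per size
#>   3 combined MCM layers, dense 64
#>   ensemble of 2 fold model(s); mean validation AUROC 1.0000

positives <- encode_dataset(pos, ens)
enr <- response_enrichment(fit, positives)
print(enr)
#> Response-enrichment motif extraction
#>   fold 2; selected filter size 4 (response score 241.4)
#>   sequence type seq8 (d_t = +1), structure type shape4 (d_t = -1)
#>   sequence-structure offset: +2 nt
#>   samples used: 400 sequence / 400 structure (dropped 0 / 0 at boundary)
#>   PWM consensus: GAUAGCAU
write_meme(enr$pwm$pwm, "rbp_demo_motif.meme", nsites = enr$sequence$n_used)
```

The fitted ensemble separates bound from unbound sequences perfectly
(validation AUROC 1.0); the planted hairpin is recovered in the structure
profile (`shape4`, shifting constant −1, i.e. just upstream of the anchor)
and the sequence–structure offset of +2 nt places the sequence motif inside
the 5' arm, as planted. The extracted PWM consensus at this miniature scale
is only partially faithful to the planted 8-mer — motif readability depends
on how strongly a single convolutional pathway consolidates during training;
the methods vignette discusses this limitation.

A command-line wrapper with the same workflow
(`simulate` / `train` / `predict` / `motifs`) is installed at
`system.file("cli", "mmcnn.R", package = "mmcnn")`.

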