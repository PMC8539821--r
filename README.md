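# sublocr

Multi-label prediction of protein subcellular localization from amino-acid
sequence and evolutionary profiles, in R with a compiled (RcppArmadillo)
network engine.

A protein may reside in several cellular compartments at once, so the task
is multi-label: for L candidate locations the model emits L independent
probabilities. `sublocr` implements a sequence model in which

* the amino-acid sequence is one-hot encoded (`l_max` x 23) and read by a
  2-layer **bidirectional LSTM**, whose per-position states form an
  `l_max` x 2h image;
* a **position-specific scoring matrix** (PSSM, consumed from PSI-BLAST
  `-out_ascii_pssm` output or precomputed tables, padded to `l_max` x 43)
  supplies evolutionary information;
* two **convolutional stacks** (4 convolution layers with 256/128/64/32
  kernels of sizes 4x3 and 3x3, three interleaved max-pooling layers,
  ReLU) extract features from the state image and the PSSM respectively;
* a fully connected layer and an elementwise **sigmoid** produce the
  per-location probabilities, trained with binary cross-entropy plus an
  L2 penalty on the convolution kernels,
  `L = -(1/n) Σ [y log ŷ + (1−y) log(1−ŷ)] + λ‖ω‖²`.

Four ablation variants are wired: `blstm` (BLSTM alone), `blstm_conv1`
(BLSTM + ConvNet1), `conv2` (PSSM + ConvNet2 alone) and `full` (both
branches concatenated).

The evaluation module implements the multi-label ranking metrics of this
literature exactly as printed — ranking loss (ties count against the
classifier), 1-based coverage, label-ranking average precision — plus
per-location F1, Matthews correlation and rank-based AUC, all verified
against brute-force enumeration in the test suite. A synthetic benchmark
generator plants location-specific sequence motifs with
conservation-structured pseudo-PSSMs so the entire pipeline is testable
without any download.

## Worked example

Generate a small motif-planted benchmark, train the compact `full` variant,
and evaluate the held-out proteins:

```r
library(sublocr)

gen <- generate_dataset(synthetic_config(n_proteins = 1000, n_locations = 6,
                                         seed = 42))
dataset_statistics(gen$data)
#> 1000 proteins, 6 locations, 1175 assignments (positive rate 19.58%)
#>  location count fraction
#>     Loc01   196    19.6%
#>     Loc02   206    20.6%
#>     Loc03   179    17.9%
#>     Loc04   199    19.9%
#>     Loc05   186    18.6%
#>     Loc06   209    20.9%
#> label multiplicity: 1:842  2:143  3:13  4:2

store <- encode_dataset(gen$data, gen$pssms,
                        encoding_config(l_max = 400,
                                        pssm_scaling = "sigmoid"))
train <- store_subset(store, store$ids[1:800])
test  <- store_subset(store, store$ids[801:1000])

model <- build_model(compact_model_config("full", n_labels = 6),
                     seed = 1, vocabulary = gen$data$vocabulary)
model <- train_staged(model, train, compact_training_config(seed = 1),
                      epochs_frozen = 4, epochs_joint = 10,
                      joint_learning_rate = 5e-3)

evaluate_all(test$labels, predict(model, test))
#> Multi-label evaluation on 200 proteins, 6 locations
#>   ranking loss       0.1664
#>   coverage           2.0550
#>   average precision  0.7452
#>   macro F1 / MCC / AUC (threshold 0.50): 0.5155 / 0.4411 / 0.8396
```

Ranking loss is the fraction of (true, false) label pairs the scores order
incorrectly (0 = perfect); coverage is how deep the score-sorted label
list must be read to find every true location (here ~2.1 of 6); average
precision is the label-ranking form (1 = every true label above every
false one); and the macro row averages the per-location binary metrics at
threshold 0.5. The model extracts most of the planted motif signal from
800 training proteins in a few minutes on one CPU core; the desk-scale
ablation in the test suite (2000 training proteins, longer staged
training) reaches held-out macro-AUC above 0.95.

The same functions scale to the published architecture — `model_config()`
defaults to `l_max` 1000, 128 LSTM units per direction and 256/128/64/32
kernels — and `run_cross_validation()` provides the fivefold protocol;
training at that scale is a GPU-class exercise and is documented in the
vignette rather than run here.

Command-line mirror of the pipeline (`simulate`, `encode`, `train`,
`crossval`, `evaluate`, `predict`):

```sh
Rscript inst/cli/sublocr.R simulate --out sim/ --n 200 --locations 6 --seed 7
Rscript inst/cli/sublocr.R encode --fasta sim/proteins.fasta \
    --labels sim/labels.tsv --pssm-dir sim/pssm --l-max 400 --out store.rds
```

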