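# emoco — momentum-contrast representation learning for animal emotion images

`emoco` is an R package for *self-supervised* analysis of animal-emotion
image collections: it learns an image embedding without using the labels,
by momentum-contrast (MoCo) training, and then classifies held-out images
with a temperature-weighted K-nearest-neighbour (KNN) monitor over that
embedding. It is aimed at researchers in animal behavior / affective
biology who have class-per-folder image datasets (e.g. the seven Panksepp
emotion systems: Exploring, Sadness, Playing, Rage, Fear, Affectionate,
Lust) but limited labeled data and limited hardware.

## The method

Two random augmentations of the same image (random resized crop,
horizontal flip, color jitter, normalization) form a positive pair. A
query encoder embeds one view into a unit vector *q*; a momentum encoder —
an exponential moving average of the query encoder,
θ_k ← m·θ_k + (1−m)·θ_q — embeds the other into *k⁺*. A FIFO queue stores
K past key vectors as negatives, and the query encoder minimizes the
temperature-scaled cross-entropy

    L_q = −ln [ exp(q·k⁺/τ) / Σ_{i=0..K} exp(q·k_i/τ) ],   k_0 = k⁺,

by SGD under a cosine-annealed learning rate. Encoders are small-image
residual networks (3×3 stride-1 stem, no stem pooling, 128-d L2-normalized
output) whose batch-normalization layers are *split* across 8 groups of
the batch, emulating multi-GPU statistics on one device. Embedding quality
is monitored per epoch by a KNN classifier (cosine similarity, K = 200,
weights exp(s/0.1)). The package also provides the in-batch NT-Xent
(SimCLR-style) variant with a LARS optimizer and warmup-cosine schedule,
an exact t-SNE export, and a supervised residual-network baseline for
comparison — plus a generator of balanced synthetic emotion-image datasets
that stands in for withheld animal photographs.

All network layers, backpropagation and optimizers are implemented in the
package (R + C++ kernels); gradients are verified against finite
differences in the test suite.

## Worked example

```r
library(emoco)

cfg <- syntheticConfig(nClasses = 7, nPerClass = 20, imageSize = 32,
                       signalStrength = 0.9, seed = 42)
ds <- generateSyntheticEmotionDataset(cfg)
ds
#> LabeledImageSet with 140 records, 7 classes
#>   classes: Affectionate, Exploring, Fear, Lust, Playing, Rage, Sadness
#>   split: 112 train / 28 test

encCfg  <- encoderConfig("resnet8", featureDim = 64, numBnSplits = 4)
mocoCfg <- mocoTrainConfig(batchSize = 28, learningRate = 0.1, epochs = 5,
                           queueSize = 256, knnK = 20,
                           imageResolution = 32, seed = 1)
res <- trainMoCo(ds, encCfg, mocoCfg)
res$history
#>   epoch train_loss knn_accuracy_pct
#> 1     0   3.023836         67.85714
#> 2     1   4.861568         67.85714
#> 3     2   5.022157         67.85714
#> 4     3   4.900318         82.14286
#> 5     4   4.821555         82.14286

chanceAccuracy(7)
#> [1] 14.28571
```

The history reports the mean contrastive training loss and the KNN-monitor
test accuracy per epoch: after five epochs on this tiny synthetic dataset
the embedding already classifies 82.1% of held-out images against a
14.29% chance baseline. (The loss *rises* while the queue fills with real
keys and then plateaus near ln(1 + K/#classes); the vignette explains this
desk-scale trajectory.) Longer runs at the package's desk-scale study
conditions — 60 images per class, 40 epochs — reach 100% KNN accuracy,
versus ≈ 70% for an untrained encoder of the same architecture.

See `vignette("momentum-contrast")` for the full model description,
parameter meanings, the synthetic-generator design and known limitations.

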