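# vitalign

Exemplar-free class-incremental learning for compact Vision Transformers,
with attention-map alignment against a frozen previous-stage snapshot.

## The problem

Image classifiers for plant disease monitoring meet new disease classes
after deployment. Retraining a network on the new classes alone causes
*catastrophic forgetting*: accuracy on previously learned classes collapses.
In the *class-incremental*, *exemplar-free* regime addressed here, the model
must discriminate among **all** classes seen so far at test time, while no
images from past stages may be stored — the only memory is the model itself
and a frozen snapshot of its previous-stage weights.

## The method

A compact ViT (patch embedding → `L` pre-norm transformer blocks of
multi-head self-attention → growing linear head on the class token) is
trained stage by stage. Inside each attention head, every query row of the
post-softmax attention matrix is a probability distribution over key
tokens. On each batch of stage `t`, the same images are forwarded through
the frozen stage-`t-1` snapshot, and the rows of the two attention stacks
are compared with the Total Variation distance

    TV(p, q) = 1/2 * sum_j |p_j - q_j|                 (in [0, 1])

accumulated over rows and blocks. The training objective is

    L_total = L_CE + lambda * L_attention

so the model learns the new classes (cross-entropy over the full grown
logit vector) while being penalized for moving its attention away from
where the previous-stage model put it. Jensen–Shannon, Hellinger
(`1/sqrt(2)` normalization) and Bhattacharyya distances are available as
ablation variants. Baseline strategies: `finetuning` (lambda = 0, the
forgetting lower bound) and `freezing` (backbone halted after stage 1).
The continual-learning score is the **Average Accuracy** after stage `t`:
the unweighted mean over stages `j <= t` of the test accuracy on stage
`j`'s classes.

Everything — the backbone, hand-derived backpropagation (verified
coordinate-by-coordinate against finite differences), AdamW/AdaMax,
training engine, metrics and a deterministic synthetic lesion-texture
benchmark — is implemented in vectorized base R.

## Worked example

```r
library(vitalign)

spec    <- synthetic_spec(seed = 42)        # 13 classes, 40 train / 20 test each
dataset <- generate_dataset(spec)
stages  <- split_classes(1:13, K = 3)       # stage sizes 5, 4, 4
config  <- train_config(strategy = "attention_alignment", seed = 1)

reports <- run_experiment(dataset, stages, config, verbose = TRUE)
```

This prints (one CPU, ~1 minute):

```
stage 1/3 [attention_alignment]: acc 0.9100  avg-acc 0.9100
stage 2/3 [attention_alignment]: acc 0.6000  avg-acc 0.5925
stage 3/3 [attention_alignment]: acc 0.3154  avg-acc 0.3308
```

Reading the numbers: after stage 1 the model classifies its first 5 disease
classes at 0.91. After stage 2 it must discriminate 9 classes without ever
revisiting stage-1 images; the average accuracy 0.59 reflects partial
retention (finetuning drops to ~0.49 here, with stage-1 accuracy at 0).
After stage 3 all 13 classes compete and forgetting dominates — the same
stability–plasticity trade-off the method negotiates at full scale, at toy
magnitude. Each `stage_report` carries the confusion matrix over classes
seen, per-class precision/sensitivity/F1, the per-stage accuracies behind
the Average Accuracy, and the per-step loss log.

## Command line

```sh
Rscript inst/cli/vitalign.R run --data synthetic --steps 3 \
    --strategy attention_alignment --distance tv --seed 1 --out results/
Rscript inst/cli/vitalign.R generate-data --out data/ --seed 5
Rscript inst/cli/vitalign.R run --data folder:data/ --steps 3 --out results2/
Rscript inst/cli/vitalign.R evaluate --checkpoint results/stage_03.rds \
    --data folder:data/
Rscript inst/cli/vitalign.R export-features --checkpoint results/stage_03.rds \
    --data folder:data/ --out features.csv
```

`run` writes per-stage JSON reports, loss CSVs, an average-accuracy curve
CSV, per-stage checkpoints and a run manifest (config + seed + package
version) into `--out`. Config files are JSON with the same nested schema as
the defaults; flags override file values; unknown keys are rejected by
name.

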