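# fermxfer

Local transfer soft-sensor modelling for fed-batch fermentation.

Key biochemical variables of a *Pichia pastoris*-type fermentation —
biomass, product (inulinase) activity, methanol concentration — are
expensive to assay and only measured off-line every few hours, while
auxiliary variables (temperature, pH, dissolved oxygen, feed rates, ...)
are logged continuously. A *soft sensor* predicts the former from the
latter. Two features of fermentation data defeat a single global
regression model:

* **multi-phase dynamics** — cell proliferation, fed-batch transition and
  protein induction phases have different data distributions, so a global
  model averages away phase-local structure;
* **batch-to-batch heterogeneity** — a new batch (different inoculum,
  feed schedule) is distribution-shifted from the historical batches the
  model was trained on.

`fermxfer` implements a local transfer modelling framework that addresses
both:

1. **Sub-source domain partitioning.** Historical source batches are
   interpolation-augmented, z-scored and PCA-reduced; K-means (cluster
   count k chosen where the SSE-versus-k curve has maximum curvature,
   i.e. the elbow) partitions the samples into phase-specific sub-source
   domains D1..DK with stored centroids, minimising the within-cluster
   sum of squares J = Σᵢ Σ_{x∈Cᵢ} ‖x − μᵢ‖².
2. **Firefly-optimized sub-models.** Each domain gets a feedforward
   sigmoid network per target variable, trained by full-batch gradient
   descent on E = ½Σ(y − ŷ)². Its hyperparameters (learning rate, hidden
   width, weight-init range, epoch budget) are chosen by an improved
   firefly algorithm: brightness I = 1/(1+L), attractiveness
   β(r) = β₀e^{−γr²}, moves xᵢ ← xᵢ + β(r)(xⱼ−xᵢ) + αε, plus stochastic
   perturbation δ(x_p − x_q), fitness-proportional crossover with the
   global best, Mantegna Lévy-flight jumps, and greedy selection.
3. **Centroid matching.** A new target batch is matched to the sub-source
   domain with the smallest Euclidean distance between its labelled
   samples and the domain centroids; individual target samples are routed
   to their nearest domain for prediction.
4. **Transfer fine-tuning.** The matched sub-model is adapted to the
   labelled early fraction of the target batch by sequential
   layer-by-layer unfreezing (output side first) with per-layer learning
   rates (frozen layers at rate 0), descending on
   L = (1/N)Σ(ŷ−y)² + w·MMD, where MMD = ‖mean(z_S) − mean(z_T)‖² aligns
   hidden-layer features of source and target inputs.

A seeded simulator of multi-phase fed-batch campaigns
(`simulate_campaign()`, `default_campaign()`) makes the whole pipeline
runnable and testable without external data.

## Worked example

```r
library(fermxfer)

# two source batches + one heterogeneous target batch
# (10 % lower inoculum, 5 % higher methanol feed)
camp <- default_campaign(kinetics_config(seed = 42))
fit  <- local_transfer_sensor(camp$source, camp$target, run_config(seed = 1))
fit
#> Local transfer soft sensor
#>   sub-source domains : 3 (sizes 124, 120, 118)
#>   matched domain     : 1 (mean centroid distances 0.794, 4.71, 5.32)
#>   frozen depth/var   : 2, 2, 2
#>   target 'batch_3': 15 labelled + 46 test samples
#>   held-out metrics:
#>   variable       rmse       r2
#>    biomass 2.39655060 0.997908
#>  inulinase 0.05574795 0.995979
#>   methanol 0.36827436 0.988067
```

Reading the output: the elbow criterion recovered the three constructed
fermentation phases (three sub-source domains of roughly equal size); the
labelled early window of the target batch was matched to domain 1 (mean
centroid distance 0.794, far below the others); per variable, two of the
three network layers stayed frozen during fine-tuning. The held-out
metrics are computed on the 46 target samples the model never saw labels
for: biomass is predicted to within ~2.4 ug/mL RMSE (R² ≈ 0.998),
inulinase activity to ~0.056 U/mL and methanol to ~0.37 g/L.

`summary(fit)` additionally reports the retained PCA components and the
firefly-tuned hyperparameters; `predict(fit, newdata)` applies the fitted
preprocessing and routed models to new auxiliary data; `plot(fit)` draws
predicted versus observed trajectories.

`benchmark_models()` reproduces the comparison design — global DNN,
classical-firefly-tuned DNN (FA-DNN), local models with centroid routing
(K-IFA-DNN), and the full transfer method (K-IFA-DNN-TL) — on identical
preprocessing, splits and seeds.

A thin command-line front end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/fermxfer.R", package="fermxfer"))')" \
  simulate --out data --batches 3 --seed 42
```

with `run` and `benchmark` subcommands operating on the batch CSVs.

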