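# recticluster

Constrained tensor clustering with exact integer programming, and
systematic ODE model selection for the resulting clusters.

## The problem

Complete multi-indexed experiments — e.g. time-resolved pERK/pAKT
phosphorylation of a panel of cell lines exposed to a panel of ligands at
several doses — form a data tensor `Z` of order *h* (the motivating
design is 36 cell lines x 14 ligands x 2 doses x 3 time points x 2
proteins). Each (cell line, ligand) pair is one *experiment*. Ordinary
clustering of the experiments can group any cells of the cell-line x
ligand grid together; the groups are then hard to read mechanistically.
`recticluster` constrains every cluster to be **rectangular** — a full
Cartesian product of a cell-line subset and a ligand subset, not
necessarily contiguous — so that each cluster states "these cell lines
respond this way to these ligands", the signature of a shared mechanism.

Two exact formulations are provided, both Boolean linear programs solved
by branch and bound to certified global optimality (gap 0):

* **direct** — over pairwise same/different-cluster indicators `X`
  constrained to an equivalence relation with rectangular classes,
  maximize `⟨S, 1−X⟩ + λ⟨1, X⟩`, where `S` is the order-2d cosine
  similarity tensor of the flattened, row-normalized data and `λ`
  controls the number of clusters;
* **refine** — given any (possibly non-rectangular) seed clustering `W`
  from any method, maximize the number of unchanged assignments
  `⟨W, Y⟩` over one-hot rectangular assignment tensors `Y`, i.e. find
  the nearest interpretable clustering to the seed.

Downstream, each cluster's mean response is screened against a
combinatorial pool of three-species receptor/pERK/pAKT crosstalk ODE
models (by default `3^6 = 729` sign patterns over the six ordered
interactions, under mass-action or Michaelis–Menten kinetics and
blocking or removal inhibition), fitted by squeeze-and-breathe Monte
Carlo search with Levenberg–Marquardt polish, and ranked by AICc.

A synthetic-data module plants rectangular ground truth with
mechanism-driven responses so the whole pipeline is testable end to end.
See the methods vignette (`vignettes/constrained-tensor-clustering.Rmd`)
for the model details, conventions and experiment designs.

## Worked example

Plant a 3-cluster rectangular partition on a 4 x 3 grid, generate noisy
data, recover the partition by the direct program, and identify cluster
1's mechanism:

```r
library(recticluster)
P0 <- sample_rectangular_partition(4, 3, 3, seed = 0)
Z  <- generate_dataset(synthetic_truth(P0, noise_sigma = 0.05, seed = 0))
Z
#> data_tensor of order 5 with shape 4 x 3 x 2 x 3 x 2
#> axes: cell_line, ligand, dose, time, protein

S <- unflatten_similarity(cosine_similarity(normalize_rows(flatten_tensor(Z, 2))))
prog <- build_direct_program(S, lambda = 0.8)
prog
#> integer_program (direct) on a 4 x 3 grid: 66 Boolean variables,
#> 822 constraint rows as built (1,896 as literally written)
res <- solve_ip(prog)
res
#> direct branch-and-bound (structural mode): 119 nodes, 0.006s,
#> status=optimal, objective=125.308, gap=0
P <- decode_direct(res, c(4, 3))
P
#> rect_partition on a 4 x 3 grid with 3 cluster(s)
#>   [1] rows {1,4} x cols {1,2,3}
#>   [2] rows {2} x cols {1,2,3}
#>   [3] rows {3} x cols {1,2,3}
rand_index(P, P0)
#> [1] 1
```

`status=optimal, gap=0` certifies a global optimum of the constrained
program; the decoded partition is exactly the planted one (Rand index 1),
including a disconnected rectangle (rows 1 and 4). Now rank three
candidate mechanisms on cluster 1's mean response:

```r
resp <- mean_response(Z, P, 1)
pool <- lapply(list(c("R->E" = "activation"),
                    c("R->A" = "activation"),
                    c("R->E" = "activation", "R->A" = "activation")), model_spec)
fits <- lapply(seq_along(pool), function(i)
  fit_model(pool[[i]], resp, options = list(bounds = c(1e-3, 10), rounds = 4,
                                            samples = 50, seed = i)))
rank_models(fits, top = 3)
#>  rank                                          model k         rss      aicc delta_aicc
#>     1 R>E:+ R>A:+ E>A:0 A>E:0 E>R:0 A>R:0 [ma/block] 5 0.001054707 -92.07279   0.000000
#>     2 R>E:+ R>A:0 E>A:0 A>E:0 E>R:0 A>R:0 [ma/block] 4 0.003684175 -83.34910   8.723693
#>     3 R>E:0 R>A:+ E>A:0 A>E:0 E>R:0 A>R:0 [ma/block] 4 0.423941110 -26.40252  65.670269
```

The dual-activation model (`R>E:+ R>A:+`, the mechanism the generator
actually planted for this cluster) ranks first with ΔAICc ≈ 8.7 over the
best single-pathway alternative; the pAKT-only model cannot reproduce the
pERK response and is far behind.

The same flow is available from a shell via the thin wrapper
`inst/cli/recticluster.R` (subcommands `synth`, `seed`, `direct`,
`refine`, `fit`, `run`), and programmatically via `run_pipeline()`, which
also writes a manifest with seeds, solver certification and content
hashes.

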