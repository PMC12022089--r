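# glossarea

Bayesian spatial-phylogenetic analysis of binary typological traits.

Languages carry binary structural features — postverbal negation, vowel
length, nominal prefixing — whose geographic distribution mixes three
signals: descent within language families, convergence between
neighbours in contact, and potentially much older gradients laid down by
prehistoric population dispersals. `glossarea` is for comparative
linguists and cultural-evolution researchers who want to separate those
signals in a languages-by-features binary matrix with missing entries,
and in particular to test whether feature probabilities follow a cline
along reconstructed dispersal paths (such as the north-to-south
peopling of the Americas from Beringia).

## The model

For language $i$ and feature $j$, a latent Gaussian variable determines
the observed value:

$$z_{ij} = \alpha_j + \beta_j\,\tilde d_i + p_j(i) + u_j(i) + \varepsilon_{ij},
\qquad x_{ij} = \mathbf 1\{z_{ij} > 0\},
\qquad \varepsilon_{i\cdot} \sim \mathcal N(0, R),$$

a multivariate probit with residual feature correlations $R$. The
phylogenetic effects $p_j \sim \mathcal N(0, \sigma_{p,j}^2
\Sigma_{\text{tree}})$ are correlated by shared branch lengths on a
rooted forest; the contact effects $u_j \sim \mathcal N(0, K)$ share one
spatial kernel $K(d) = \sigma_{sp}^2 k(d/\ell)$ over topographic
least-cost distances but are realised independently per feature; and
$\tilde d_i$ is the standardised distance from the entry point along
dispersal trajectories. Three nested specifications: **Model 1** has
phylogeny and contact only; **Model 2** adds the expansion slope
$\beta_j$; **Model 3** additionally replaces $D_i$ by $D_i + \delta_i$
with strictly positive half-Cauchy measurement errors $\delta_i$,
acknowledging that present-day locations mismeasure the distance a
lineage actually travelled. Fitting is by an augmented Gibbs sampler
with collapsed Gaussian-process updates (see the methods vignette,
`vignettes/spatial-phylogenetic-probit.Rmd`).

Around the model sit the stages that turn posteriors into results:
least-cost distance construction over elevation rasters with a
choke-point composition between continents, a synthetic-data generator
with known ground truth, tenfold cross-validation in two schemes scored
by balanced accuracy, a 10,000-replicate null-coefficient simulation,
grid marginal-effect maps with PCA-to-RGB compression and hierarchical
clustering, posterior-overlap and feature-stability summaries, and an
asymmetric source-to-target test for secondary expansions.

## A worked example

Simulate a 40-language, 6-feature dataset from Model 3 with two planted
expansion effects ($\beta_1 = 1.5$, $\beta_4 = -1$), refit it, and
summarise the slopes:

```r
library(glossarea)

params <- generative_params(n_lang = 40, n_feat = 6,
                            beta = c(1.5, 0, 0, -1, 0, 0),
                            sigma_phylo = 0.6, sigma_sp = 0.6,
                            lengthscale_sp = 2e6, seed = 7)
ds <- simulate_dataset(params)

m <- assemble_model(model_spec(model = 3), ds$traits, ds$distances,
                    ds$phylogeny)
post <- fit(m, chains = 2, iterations = 800, seed = 2)
coefficient_summary(post)
```

```
  feature   mean lower  upper p_positive zero_overlap
1     F01  1.617  0.56  2.717      0.999         TRUE
2     F02  0.019 -0.77  0.879      0.506        FALSE
3     F03  0.089 -0.56  0.860      0.585        FALSE
4     F04 -0.821 -1.69 -0.048      0.019         TRUE
5     F05  0.293 -0.37  1.050      0.767        FALSE
6     F06  0.600 -0.26  1.557      0.916        FALSE
```

Both planted slopes are recovered with the right sign and 95% credible
intervals excluding zero (`zero_overlap`), while the four null features
overlap zero. `mean` is the slope per standard deviation of
distance-to-entry on the latent probit scale: feature F01's probability
of being present rises by roughly $\Phi(1.6/2) - \Phi(-1.6/2) \approx
0.58$ between languages two standard deviations apart along the
corridor. `p_positive` is the posterior probability of a positive
slope.

The inter-rater quality-control helper reproduces double-coding
percentages from raw counts:

```r
interrater_stats(154, 19, 13)
#> $codability_pct  12.3
#> $value_pct        8.4
```

Meaning: of 154 double-coded datapoints, coders disagreed on whether a
feature was codable at all in 12.3% of cases, and on the coded value in
8.4%.

A command-line wrapper (`exec/glossarea`) exposes the pipeline stages
(`simulate`, `distances`, `fit`, `map`, `cluster`, `cv`, `nullsim`,
`secondary`), each writing its artifacts plus a JSON run manifest.

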