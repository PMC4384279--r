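# promleak

Stochastic gene expression with promoter leakage and auto-regulation.

Most telegraph-type models of gene expression assume the inactive promoter
state is silent. Real promoters leak: basal transcription continues at a low
rate while the promoter is nominally OFF. `promleak` is for researchers in
stochastic gene expression and synthetic biology who want to quantify what
that leakage does to a gene's noise, its copy-number distribution, and its
bursting kinetics — in the presence of positive or negative auto-regulation.

## The model

A promoter switches between states $D_0$ and $D_1$; the gene product $P$
(one-step transcription–translation) is made in both states and feeds back
on the switch catalytically:

$$D_0 \xrightarrow{\gamma_1} D_1,\quad D_1 \xrightarrow{\gamma_0} D_0,\quad
  D_1 + P \xrightarrow{f} D_0 + P,\quad
  D_1 \xrightarrow{\lambda_1} D_1 + P,\quad
  D_0 \xrightarrow{\lambda_0} D_0 + P,\quad
  P \xrightarrow{d} \varnothing.$$

The smaller synthesis rate is the leakage rate. With $\lambda_1 \gg
\lambda_0$ the feedback is negative ($D_1$ ON); with $\lambda_0 \gg
\lambda_1$ it is positive ($D_0$ ON). All rates are normalized by $d$.

Three independent routes to the stationary behaviour are provided and
cross-validated against one another:

* **Closed form** — the stationary law $P(n)$ as a finite superposition of
  Kummer functions ${}_1F_1$, plus generating-function moments and the
  noise intensity $\eta_n^2 = \sigma_n^2/\langle n\rangle^2$
  (`stationary_pmf()`, `moments()`).
* **Truncated chemical master equation** — a sparse null-space solve over
  the promoter-resolved state space, the package's ground truth
  (`cme_steady_state()`).
* **Exact simulation** — direct-method Gillespie in C++, with slow
  transcription-factor-binding and two-stage transcription/translation
  variants (`simulate_gene()`), and burst extraction from promoter dwell
  times (`empirical_burst()`).

Scan drivers (`noise_vs_leakage_scan()`, `modality_scan()`,
`burst_scan()`) reproduce the three headline phenomena: leakage always
lowers expression noise (even at fixed mean, however the mean is fixed),
leakage unimodalizes bimodal distributions, and leakage produces fewer
bursts through the feedback loop. A thin CLI (`exec/promleak`) exposes all
of it with TSV output.

## Worked example

The canonical no-feedback regime ($\gamma_1 = 0.2$, $\gamma_0 = 0.1$,
$\lambda_1 = 40$, no leakage), then the same gene with leakage
$\lambda_0 = 25$:

```r
library(promleak)
p <- gene_params(gamma1 = 0.2, gamma0 = 0.1, f = 0, lambda1 = 40, lambda0 = 0)
moments(p)
#> <moment_summary> mean 26.6667, variance 300.171, noise 0.422115
count_modes(stationary_pmf(p))
#> <modality_report> 2 mode(s) at {0, 39}

p25 <- set_leakage(p, 25)
moments(p25)
#> <moment_summary> mean 35, variance 73.4615, noise 0.0599686
count_modes(stationary_pmf(p25))
#> <modality_report> 1 mode(s) at {38}
```

Leakage raised the mean from 26.7 to 35 molecules, cut the noise intensity
seven-fold (0.42 to 0.060), and collapsed the bimodal distribution (one
phenotype near zero, one near the ON level) into a single peak — the
phenotypic-simplification effect in miniature.

Bursting, from an exact simulation of $10^5$ product lifetimes, against
the dwell-time closed forms $\langle BF\rangle = \gamma_1$,
$\langle BS\rangle = \lambda_1/\gamma_0$:

```r
tr <- simulate_gene(p, t_end = 1e5, seed = 1)
empirical_burst(tr)
#> <burst_summary> BF 0.198, BS 406.2, tau_on 10.15, tau_off 5.05 (5919 bursts observed)
theoretical_burst(p)
#> <burst_summary> BF 0.2, BS 400, tau_on 10, tau_off 5
```

The same from a shell:

```sh
exec/promleak scan-modality --gamma1 0.2 --gamma0 0.1 --lambda1 40 --grid 0,25,3
```

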