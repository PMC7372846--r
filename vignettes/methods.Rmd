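---
title: "Semi-parallel logistic GWAS under approximate homomorphic encryption: models, circuits and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-parallel logistic GWAS under approximate homomorphic encryption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hegwas)
```

## The statistical problem

A case/control association study observes a binary phenotype $y_i$, a small
set of covariates $X_i \in \mathbb{R}^k$ (intercept included) and $p$ binary
SNP indicators $s_{ij}$ for $n$ subjects.  For each SNP $j$ the model of
interest is the logistic regression of $y$ on $(X, s_j)$, and the quantity
released is the Wald test of the SNP coefficient.  Fitting $p$ separate
logistic regressions under encryption is prohibitive, so the package
implements the *semi-parallel* shortcut: fit the covariate-only model once,
then take a single Newton (IRLS) step per SNP, vectorized across all SNPs.

Writing $\hat y_i = X_i^\top \beta_X$, $p_i = \sigma(\hat y_i)$,
$w_i = p_i(1-p_i)$ and the weighted working response
$(Wz)_i = w_i \hat y_i + (y_i - p_i)$ (with $y_i$ as the 0/1 indicator), the
one-step coefficient for SNP $j$ follows from the block inverse of the
Fisher information $U^\top W U$, $U = (X\,|\,s_j)$:

$$
\beta_j \;=\;
 \frac{|A| \; s_j^\top W z \;-\; b_j^\top\, \mathrm{adj}(A)\, X^\top W z}
      {|A| \; c_j \;-\; b_j^\top\, \mathrm{adj}(A)\, b_j},
\qquad
A = X^\top W X,\;\; b_j = X^\top W s_j,\;\; c_j = s_j^\top W s_j .
$$

The numerator $\beta_j^{*}$ and denominator $\beta_j^{\dagger}$ are exactly
what the encrypted circuit outputs, together with $|A|$; the Wald statistic
is $z_j = \beta_j^{*}/\sqrt{|A|\,\beta_j^{\dagger}}$ and the p-value is the
two-sided normal tail $2(1-\Phi(|z_j|))$ (the only reading of the normal
tail that yields probabilities in $[0,1]$; no multiple-testing correction is
applied by default, matching the raw-cutoff reporting convention of this
method family).  Division never happens under encryption: the adjugate form
replaces the matrix inverse, which is why $k$ must stay small (2--6; the
linearized minor layout grows as $(k-1)!$).

`semi_parallel_plain()` implements this in the clear, in an exact-sigmoid
variant (the statistical reference) and a cubic-polynomial variant (the
bit-for-bit oracle of the encrypted circuit).  `fit_full_logistic()` is the
per-SNP IRLS gold standard built on `stats::glm.fit`.

## The encryption scheme

The encrypted backend is a leveled approximate scheme for fixed-point real
vectors over the negacyclic ring $R = \mathbb{Z}[X]/(X^N+1)$, $N$ a power of
two, in full residue-number-system form.  A ciphertext at level $\ell$ lives
over the primes $\{q_0, \ldots, q_{\ell-1}\}$; each level prime is the
NTT-friendly prime nearest $2^\eta$ so that a rescaling divides the
encrypted message by almost exactly $2^\eta$.  Key switching uses the
decomposition of the target polynomial into its per-prime residues combined
with a single special modulus $p_0$: each switching-key component carries
$p_0 B_i s_1$ (with $B_i$ the CRT unit of $q_i$), the accumulated products
are divided by $p_0$ with exact balanced rounding, and the noise added per
switch stays at the size of a fresh encryption error.  This trades more NTT
work per switch for a much smaller modulus than the classical
equal-size-special-modulus approach, which is the right trade-off at the
moderate depths used here.  Linear arithmetic over *extended* (degree-two)
ciphertexts is supported so that sums of raw products pay for one key switch
in total (lazy key switching); the circuit uses this in every inner-product
accumulation.

Design points fixed here because the construction leaves them open:

* **Rounding.** Balanced-representative rounding $(x - [x]_{p_0})/p_0$ with
  $[x]_{p_0} \in (-p_0/2, p_0/2]$; since $p_0$ is odd, ties cannot occur.
* **Randomness.** Keys, encryption vectors and errors come from a
  self-contained seeded generator (xoshiro-type stream, Box--Muller rounded
  Gaussian of standard deviation 3.2, ternary secrets by rejection
  sampling), so key material and ciphertexts are reproducible across
  platforms.  An OS-entropy mode is deliberately absent from the tested
  surface.
* **Scale bookkeeping.** The tracked scale is updated by the *true* chain
  primes, identically on both backends.  Addition requires exact level
  equality and scale agreement within a relative $10^{-4}$; the drift
  between $q_i$ and $2^\eta$ accumulates to at most $\sim 2^{-18}$ across a
  full-depth circuit, so genuine misuse (wrong scale by factors of
  $2^\eta$) still fails loudly while legitimate operand pairs pass.
* **Rotation keys** are generated for a declared amount set (the pipeline
  declares $\pm 2^t$); other amounts are composed from the binary expansion
  of the requested rotation.
* **Encoded plaintexts** (constants, masks, trivial encryptions) are split
  into two 40-bit limbs per coefficient, so constants can be attached at
  scales up to $\sim 2^{100}$ without integer overflow.

The **slot emulator** exposes the identical operation surface on plain
length-$N/2$ vectors with the same level/scale metadata and the same
contract violations, but exact values.  Every circuit in the package runs
unchanged on either backend; the emulator is the correctness oracle, and
backend agreement is measured as the maximum slot difference relative to
the magnitude of the packed vector (packed outputs legitimately contain
exact zeros, where entrywise ratios are meaningless).  Per-operation noise
tolerances in the tests were set empirically at roughly an order of
magnitude above observed maxima on the small preset.

## Packing and the circuit

The client packs the data once:
$E(x_{i\ell} S_i)$ per sample and covariate column (the $\ell = 1$ family is
the SNP matrix itself, since $x_{i1} = 1$); $E(y^\top X)$ and $E(X)$ with
$N_2/(kn)$ copies of each sample row; $E(y)$ with $N_2/n$ copies of each
phenotype indicator; the covariate columns in the same layout (used for the
determinant's first-row expansion); and the signed minor vectors of each
per-sample covariance $X_i^\top X_i$, computed in the clear before
encryption.  SNP panels wider than $N_2$ split into independent slot blocks
over which the per-SNP steps map.

Two packing details differ deliberately from the idealised description:

* The $(k-1)!$-slot minor unit is zero-padded to the next power of two
  (8 slots for $k=4$).  The integer copy count $N_2/(n\,(k-1)!)$ simply does
  not exist for non-power-of-two factorials, and power-of-two periodicity is
  what makes the final rotate-and-sum of the adjugate land constant in
  every slot; the padded slots carry exact zeros through the product tree.
* Power-of-two padding of $n$ uses all-zero rows (intercept included), which
  vanish from every aggregate.  Padding $k$ with an all-zero column would
  make $A$ singular, so padded columns contribute a unit diagonal entry to
  the packed covariances instead: $\beta^{*}$, $\beta^{\dagger}$ and $|A|$
  all scale by the same factor, and every coefficient, Wald statistic and
  p-value is unchanged -- a property the test suite checks rather than
  assumes.

The pipeline consumes levels exactly as planned: covariate training
(below), two levels each for the replicated predictions and the cubic
sigmoid, one each for the weights and working response, $s+1$ for the
hybrid replication into per-sample constants, one multiplication each for
the $B_\ell$, $s_j^\top Wz$ and $X \odot Wz$ aggregations,
$1 + \lceil\log_2(k-1)\rceil$ for the adjugate product tree (odd factor
counts padded with trivial encryptions of ones), and two for the final
double sums, which accumulate all $k^2$ terms lazily and relinearize once.
`level_plan()` computes the whole schedule; the circuit records realized
levels and `check_level_trace()` asserts integer equality.  Release masking
(`apply_mask()`) multiplies the outputs by random factors with
$(r^{*})^2 = r^{\dagger} r_A$, leaving $z$ and $p$ invariant; it costs one
constant multiplication, so enable it by running with one level above the
planner minimum.

## Covariate training in four levels per iteration

Training uses Nesterov-accelerated gradient descent on the covariate-only
model, $\sigma$ replaced by the cubic
$\sigma_3(x) = 0.5 + 0.15012x - 0.001593x^3$ (global least-squares fit on
$[-8, 8]$; worst error $\approx 0.1$ near $|x| \approx 2$, which the
one-step correction tolerates).  Starting from zero, the first iteration is
a single constant multiplication because $\sigma_3(0) = 1/2$ exactly.  Each
further iteration costs exactly four levels: inner products, two levels of
masked polynomial evaluation, and the product with the packed data.  The
momentum combination $u = (1+\lambda)\beta_t - \lambda\beta_{t-1}$ never
appears on the critical path: its scalars distribute over the three
squared/cross products of the two per-iterate inner-product ciphertexts and
fold into the constant multiplications of the polynomial evaluation, while
the additive state update runs one constant multiplication deep *in
parallel* with the four-level gradient path.  This keeps
$\mathrm{lvl}(\beta_X) = L - (4(\textit{NumIter}-1)+1)$ for any iteration
count.

The step schedule is the package's own choice (any schedule fitting the
four-level budget is admissible, and the clear-text oracle uses the same
one): $\gamma_t = 10/(t+1)$ with the standard accelerated-gradient momentum
sequence $\lambda_t = (a_t - 1)/a_{t+1}$,
$a_{t+1} = (1 + \sqrt{1+4a_t^2})/2$, $a_1 = 1$.  On min/range-normalized
covariates in $[0,1]$ this is well inside the stable region and after two
iterations yields covariate fits good enough that the one-step SNP
statistics track the fully iterated gold standard (F1 $\ge 0.95$ at all
reported cutoffs on the shipped fixture).

```{r plan}
level_plan(num_iter = 2, s = 4, s_prime = 0, k = 4,
           params = he_preset("set2"))
```

## Parameter presets

Three production presets cover one to three training iterations; all use
ternary secrets, error standard deviation 3.2, and 128-bit-security
parameters asserted against the embedded standardization table (ciphertext
modulus excluding the special prime against the per-dimension bound; no
lattice estimator is run).  `set2_small` keeps the full Set-II level
structure at ring dimension $2^{13}$ for fast testing and is flagged
insecure-for-research.  The nominal modulus totals are
`r total_modulus_bits("set1")`, `r total_modulus_bits("set2")` and
`r total_modulus_bits("set3")` bits.

Phenotype coding deserves a note: the training loss is the $\pm 1$ logistic
log-likelihood (so the packed $E(y^\top X)$ carries signed rows), while the
working response of the Newton step uses the 0/1 indicator that matches
$p_i = \Pr[y_i = 1]$.  Both codings are accepted on input and mapped
internally; using $\pm 1$ inside $y - p$ would bias every statistic, which
is visible immediately against the `glm` gold standard.

## The synthetic cohort generator

`simulate_gwas_data()` emulates the structure of a small clinical GWAS
cohort: defaults of $n = 245$ samples, $p = 1024$ SNPs, $k = 4$ (intercept
plus age/weight/height analogues on natural scales with ~2% missing cells,
mean-imputed and min/range-normalized to $[0,1]$), per-SNP allele
frequencies uniform on $[0.05, 0.5]$, ten planted causal SNPs of log-odds
effect 3, covariate effects $(0.4, -0.6, 0.5)$ on the normalized scale, and
an intercept centring the expected logit at zero.  SNPs are independent
Bernoulli columns: no linkage disequilibrium, population stratification or
Hardy--Weinberg structure.  Passing tests therefore demonstrate numerical
and statistical correctness of the *method* under an idealised cohort --
correlated markers or stratified populations would affect the science of a
real analysis, but not the encrypted arithmetic being verified.

## What the tests establish, and at what sizes

* Exact reproduction of the modulus-chain totals and the full level
  schedule, including the runtime trace of the circuit (integer equality).
* Emulator circuit versus plaintext semi-parallel oracle: agreement to
  $\sim 10^{-13}$ on 20 seeded cohorts of $n = 16$, $k = 4$, $p = 64$
  (sizes chosen to exercise every packing boundary while keeping the full
  suite under a minute).
* Real ciphertexts at `set2_small` versus the emulator: $\sim 10^{-6}$
  relative on the same fixture, against a $10^{-3}$ requirement.
* The adjugate form equals the direct one-step Newton solve to $10^{-9}$
  over random designs with $k \le 5$, and the minor-index scheme
  reconstructs $|A| A^{-1}$ to $10^{-9}$.
* Statistically: null type-I within three binomial standard errors of 0.05
  at $n = 500$, $p = 2000$; a planted effect of 3 at allele frequency 0.3
  reaches $p < 10^{-4}$ in $\ge 90\%$ of 50 seeds; F1 against the IRLS gold
  standard $\ge 0.95$ at cutoffs $10^{-2}..10^{-5}$ on the $n = 245$,
  $p = 1024$ fixture.

```{r demo}
ds <- simulate_gwas_data(n = 16, p = 64, k = 4, n_causal = 2,
                         effect_size = 2, missing_rate = 0, seed = 3)
run <- run_gwas(ds, backend = "emulator", preset = "set2_small")
all(run$trace_check$match)
head(run$result[order(run$result$pvalue), c("snp", "beta", "z", "pvalue")], 3)
```

## Known limitations

* $k \le 6$: the adjugate linearization grows factorially; large covariate
  sets (principal components, many clinical variables) are out of reach of
  this inversion strategy.
* One Newton step per SNP; strong SNP effects with a poor covariate-only
  baseline would need further iterations that the level budget does not
  include.  SNP--SNP interaction models are out of scope.
* Degree-3 sigmoid: inputs far outside $[-8, 8]$ (unnormalized covariates,
  extreme separation) degrade the approximation silently.
* Binary genotype coding is assumed by the $c_j = b_{1j}$ identity inside
  the circuit; \{0,1,2\} dosages are accepted only by the clear-text
  oracles, behind an explicit flag.
* The encrypted backend is a reference implementation tuned for
  auditability (coefficient-domain polynomials, per-call NTTs); it is
  single-threaded and makes no constant-time or side-channel claims.
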