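# paleodiv

Hill-number diversity estimation for paradigmatically classified artifact
assemblages, built around the Early Paleoindian fluted-point record of
North America.

## The problem

Were the stone points of the earliest Paleoindians more diverse east or
west of the Mississippi? Raw counts of observed point forms cannot answer
this: the two regional samples differ in size and in completeness, and a
larger or more complete sample always reveals more forms. `paleodiv`
applies the estimation machinery of modern biodiversity statistics to
artifact classes so the comparison can be made fairly.

Specimens are placed into **paradigmatic classes** -- each class the
intersection of one state per morphometric character, over seven
quantitative characters spanning 1944 possible classes. For a regional
sample with class abundances \(X_i\) (total \(n\)), the package estimates:

- **Hill numbers** \({}^qD = (\sum_i p_i^q)^{1/(1-q)}\) for
  \(q = 0, 1, 2\) -- class richness, the exponential of Shannon entropy
  (effective common classes), and inverse Simpson concentration (effective
  dominant classes) -- observed and asymptotic (bias-corrected Chao1, the
  low-bias nonparametric entropy estimator, and the unbiased repeat-rate
  estimator);
- **sample coverage** via the improved Good–Turing estimator
  \(\hat C = 1 - \frac{f_1}{n}\frac{(n-1)f_1}{(n-1)f_1+2f_2}\), from the
  singleton and doubleton counts \(f_1, f_2\);
- **seamless rarefaction/extrapolation curves** on both sample-size and
  coverage bases, with bootstrap confidence bands (200 replicates by
  default);
- the **coefficient of variation of class abundances** (heterogeneity)
  through the coverage-driven Chao–Lee estimator;
- **Sørensen-weighted class-sharing networks** between assemblages, with
  density, components and isolates.

A synthetic-data generator with full ground truth (`assemble_dataset()`)
emulates the two-region study structure so every pipeline stage is testable
without the original specimen-level dataset.

## Worked example

The published regional frequency tallies ship with the package: 154 points
in 71 classes in the West, 138 points in 88 classes in the East.

```r
library(paleodiv)
fc <- clovis_freq_counts()
run_diversity(fc, dialect = "freqcounts", B = 200, seed = 1)
```

```
<diversity report>
  region   n S_obs coverage cv_hat q           measure observed asymptote   se ci_low ci_high
1   East 138    88    0.567  0.632 0    Class richness     88.0     207.1 40.5  127.7   286.5
2   East 138    88    0.567  0.632 1 Shannon diversity     74.6     158.9 19.8  120.1   197.6
3   East 138    88    0.567  0.632 2 Simpson diversity     61.8     111.2 17.0   77.8   144.6
4   West 154    71    0.689  1.387 0    Class richness     71.0     214.1 53.2  109.7   318.4
5   West 154    71    0.689  1.387 1 Shannon diversity     45.4      84.0 13.0   58.6   109.4
6   West 154    71    0.689  1.387 2 Simpson diversity     28.9      35.3  5.2   25.0    45.5
```

Reading the table: the eastern sample is *less* complete (coverage 56.7%
vs 68.9%) yet shows both higher observed diversity at every order and
higher asymptotic Shannon and Simpson diversity, with non-overlapping
intervals for those two orders -- the East used a significantly more
diverse set of point forms among its common and dominant classes. The CV
column shows the converse pattern in evenness: western class frequencies
are strongly skewed (CV 1.387: a few forms dominate), eastern ones nearly
even (CV 0.632). `report$curves` holds the size- and coverage-based
rarefaction/extrapolation curves behind the same comparison.

Starting from specimen measurements instead:

```r
cl <- classify_points(read_specimens("specimens.csv"))   # 7-character classes
run_diversity(cl, dialect = "classified", B = 200, seed = 1, out_dir = "out")
```

which also builds the class-sharing network (density, components,
isolates, cross-region shared classes) and writes the full report bundle.

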