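---
title: "Simulating AI-prioritized radiology worklists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating AI-prioritized radiology worklists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triagesim)
```

## The question and the model

Radiology worklists are conventionally read first-in, first-out (FIFO), so
a pneumothorax waits exactly as long as a normal follow-up film. If a
multi-label classifier screens every chest X-ray (CXR) at acquisition, the
worklist can instead be ordered by predicted urgency. `triagesim` is a
discrete-event Monte Carlo model of that workflow, designed to quantify the
effect of the reordering policy — not of the classifier's imaging internals,
which enter only through their error rates.

One simulated day couples four stochastic components:

1. **Arrivals.** Exam acquisition times accumulate from midnight by
   inter-arrival gaps drawn from an hour-of-day-conditioned discrete
   distribution; generation stops at minute 1440 but the radiologist works
   on until the list is empty, so days are independent replications.
2. **Ground truth.** Each exam carries eight binary findings drawn
   independently with its institution's prevalences; an exam with none is
   "normal".
3. **Prediction.** Per finding, the classifier fires with probability TPR
   on true positives and FPR on true negatives, independently across
   findings and exams. The exam's queue rank is the most urgent predicted
   finding (rank 1 = pneumothorax ... rank 8 = foreign object, 9 = nothing
   predicted).
4. **Service.** One radiologist finalizes reports separated by gaps drawn
   from a second hour-conditioned distribution, which absorbs everything
   the data contain — pauses, phone calls, shift effects. A completion
   that meets an empty list is discarded; the service chain restarts with
   a fresh gap at the next arrival.

Policies: `fifo`, `prio` (stable priority insertion: an exam goes behind
all pending exams of equal-or-better rank, so ties stay chronological),
`prio_maxwait` (additionally, at every event, any exam waiting longer than
`t_max` is promoted to a front tier, oldest first), and `perfect`
(prioritization by true labels — the attainable upper bound).

The outcome is the report turnaround time (RTAT), reported per class:
an exam contributes to every class whose finding it truly carries,
whatever was predicted, so classifier errors show up as displaced RTAT
rather than misfiled exams.

## Timing distributions and their synthesis

Delta histograms use 1-minute bins with integer edges on the support
(0, 150]; a gap d lands in bin `ceiling(d)` attributed to the hour of the
*earlier* event, and a draw from bin j returns j minutes. Gaps above
150 minutes (2 h 30 min) are discarded as outliers when building from
timestamps — they encode downtime, not workflow speed. Empty hour rows
fall back to the pooled all-hours distribution at sampling time so the
clock can never stall.

Real per-hour histograms of this kind are institution data and rarely
published, so the package ships a synthetic generator that emulates their
salient structure:

* arrival gaps: lognormal (or gamma) with mean 12 min during day hours
  [07, 19) and 45 min at night, coefficient of variation fixed at 1 — the
  near-memoryless regime typical of uncoordinated arrivals;
* reporting gaps: one lognormal for all hours, dispersion (sdlog) 0.75,
  heavy-tailed enough to carry interruptions and breaks;
* each hour row is the family discretized to the 1-minute bins, truncated
  to (0, 150] and renormalized, stored as expected counts of 1e6 draws —
  construction is therefore deterministic, and all randomness lives in the
  sampling streams.

The one free scale, the reporting mean, is set by **calibration**:
`calibrate_reporting_mean()` bisects it until a FIFO run (100 days, fixed
evaluation seed) reproduces a target grand-mean RTAT of 80 minutes — a
measured hospital average for CXR. The calibrated default is 13.266 min,
which puts the day shift slightly above saturation (day arrivals every
12 min), so a backlog builds through the day and drains at night; that
load regime, not any single parameter, is what the calibration pins down.
With it, simulated FIFO grand means stay within a few percent of 80 across
seeds.

## The classifier surrogate

Only operating points matter to queue order. Two presets are bundled:
`lowFPR` (every finding thresholded at FPR 0.05, TPRs 0.82/0.71/0.86/
0.75/0.61/0.75/0.51/0.51 in urgency order) and `lowFNR` (every TPR 0.95,
FPRs 0.20/0.24/0.21/0.27/0.39/0.18/0.72/0.78). For sweeping the threshold
continuously, the equal-variance binormal ROC family
`TPR = pnorm(sqrt(2) * qnorm(AUC) + qnorm(FPR))` is the standard minimal
one-parameter surrogate; `default_roc()` derives each finding's AUC by
inverting this curve at both presets and averaging the two implied
separations, rather than hard-coding AUCs. The sweep applies one common
FPR to all findings, mirroring how the presets fix a single rate across
findings; at FPR 0 nothing is flagged and at FPR 1 everything is, so both
endpoints provably collapse to FIFO — in this implementation exactly,
record for record, because the policies share random streams.

## Randomness and reproducibility

A single master seed expands deterministically (Lehmer-style mixing) into
four named streams — arrival, labels, classifier, service — each further
split per day. Two consequences: a run is bit-for-bit reproducible from
its config (what the run manifest stores), and two strategies run under
the same master seed see identical exams, labels and predictions — common
random numbers, so strategy contrasts are paired and tight.

Numerical conventions worth stating: completions process before arrivals
at equal clock times (this guarantees RTAT > 0); the post-stall service
gap is sampled at the arrival that restarts the chain, at that arrival's
clock hour; promotion is evaluated at events only, which is sufficient
because nothing can be popped between events; promoted exams order by
acquisition time, the natural aging rule, and `prio_maxwait`'s threshold
defaults to 360 min — a 6-hour guarantee chosen as a round clinical bound,
since no canonical value exists. Times are serialized with three decimals
for stable CSV diffs.

## What the defaults do and do not show

With the default conditions the simulation reproduces the qualitative
findings that motivate smart worklists: FIFO is class-blind (~80 min for
every class); `prio` at the `lowFPR` point cuts the pneumothorax average
by roughly a factor of three while more than doubling the normal-class
average; the pneumothorax *maximum* RTAT grows (false negatives sink), and
`prio_maxwait` pulls the maxima of all classes below the plain-`prio`
tail for only a small increase of the urgent-class mean; `perfect` orders
class averages exactly by urgency. The FPR sweep of the most urgent class
is U-shaped with an interior optimum. Where the optimum falls depends on
the load regime: under the calibrated defaults it sits at FPR ~0.1–0.2,
at higher loads it moves toward small FPRs — the sweep's shape, not the
argmin's exact position, is the robust statement.

Test and evaluation scale was chosen to keep the full suite in a few
minutes on one core: the end-to-end property checks run ~1350 simulated
days (~1e5 exams) per strategy and 400 days per sweep point; statistical
assertions use 3-sigma bands or Welch tests at those sizes.

Deliberate simplifications, shared with the workflow being modelled or
forced by what is publishable: one machine, one radiologist, no weekday
structure; findings sampled independently (under the bundled prevalences,
independence gives ~11.6% label-free exams, whereas the annotation sample
that yielded those prevalences reports 31% normals — the marginals and the
normal rate cannot both be honored without a co-occurrence model, which is
not available); classifier errors independent across findings with zero
inference latency; no preemption of a report in progress; severity grades
and referrer-assigned priorities are out of scope. Conclusions should be
read as *policy contrasts under a calibrated load*, not as predictions of
any particular institution's absolute minutes.
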