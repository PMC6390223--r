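# graspbias

Where do people place their fingers when they pick things up? When grasping
an elongated object with a precision grip (thumb and index fingertip),
humans show a systematic spatial bias: the grasp centre — the midpoint
between the two fingertip contacts — lands off the object midline. Two
hypotheses compete to explain the bias. **Object visibility**: actors grasp
on the side of the acting hand, so the hand occludes less of the object.
**Minimum reach**: actors grasp toward whichever end shortens the reaching
movement, minimising energy expenditure.

`graspbias` implements a reanalysis pipeline that decides between the two
using a cylinder-orientation design in which the hypotheses decouple. For a
right hand starting to the right of the object, at a 150° cylinder rotation
both hypotheses predict a bias toward the same (rightward, near) end; at
60° they predict **opposite** sides of the midline. The pipeline:

1. excludes degenerate "long-axis" grasps (thumb–index axis within 45° of
   the cylinder's long axis, i.e. grips on the ends);
2. computes each participant's **medoid** grasp per orientation — the grasp
   minimising its summed distance to the participant's other grasps, so the
   summary is always an actually observed grasp — and the group medoid
   across participants;
3. measures the bias *b* at 150° as the signed long-axis deviation *u* of
   the medoid grasp centre from the midline;
4. builds the two predicted grasps at 60°, at `u = s·b` with the side `s`
   from each hypothesis (visibility: the acting-hand side, the axis end
   with larger x for a right hand; reach: the side minimising the
   Euclidean start-to-grasp distance), with contacts perpendicular to and
   on the cylinder surface;
5. computes each participant's distance from their 60° medoid to each
   prediction and compares the paired distance vectors with a two-sided
   paired-samples t-test: the winner is the hypothesis with the smaller
   mean distance, declared only when p < α (default 0.05).

A synthetic generator (`generate_dataset()`) reproduces the study design —
14 participants × 4 materials × 5 repetitions at 150° and 60°, a
truncated-normal population of participant biases, per-digit motor noise,
and a 4% rate of long-axis grasps — so the whole pipeline is verifiable by
parameter recovery without the original motion-capture data.

## Worked example

The `analysis/` scripts run the workflow end to end
(`Rscript analysis/01_simulate.R`, then `02_analyze.R`, then
`03_parameter_recovery.R`). The core of it:

```r
library(graspbias)

records <- generate_dataset(sim_config(seed = 1905))  # or load_records(path)
result  <- run_analysis(records, analysis_config(), verbose = TRUE)
print(result)
```

```
560 records at the analyzed orientations; 24 long-axis grasps excluded (4.3%)
retained trials per participant: 35-40
Grasp-bias hypothesis comparison (14 participants)
  long-axis grasps excluded: 4.3%
  bias at 150 deg (mean signed deviation): -1.463 cm [source: per_participant]
  mean distance to visibility prediction: 0.292 cm
  mean distance to reach prediction:      2.904 cm
  t(13) = -9.506, p = 3.23e-07 (alpha = 0.05)
  winner: visibility
```

Reading the output: at 150° the mean signed deviation is −1.46 cm — the
negative axis end, which at 150° is the rightward, acting-hand side, as
both hypotheses predict. Transferred to 60°, the participants' grasps sit
0.29 cm from the visibility prediction but 2.90 cm from the reach
prediction; the paired t-test on the 14 distance pairs is decisive (the
negative t means distances to the visibility prediction are the smaller),
so the pipeline declares the visibility hypothesis the winner — correctly,
since this dataset was generated under it. `report(result, path)` writes
the same numbers as JSON plus a text block.

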