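# Report bundle data dictionary

## participant_measures.csv
One row per participant x task.

| column | meaning |
|---|---|
| participant_id | opaque identifier |
| group | ASD or TD |
| covariate | nonverbal developmental score (dimensionless) |
| task | RJA, IJA1 or IJA2 |
| n_trials | trials presented for this task |
| n_usable | trials surviving both exclusion criteria |
| n_first_target / n_first_nontarget | usable trials whose first JA-phase object look landed on the target / non-target |
| norm_accuracy | (n_first_target - n_first_nontarget) / (sum); empty when no object look |
| t_face_target, t_target_face, t_face_non_target, t_non_target_face | per-trial mean transition counts over usable trials (JA phase) |
| t_between_objects | per-trial mean of target<->non-target transitions, both directions pooled |
| total_* | the corresponding totals across usable trials |
| norm_transition_score | RJA: (face->target - face->non-target)/(sum of both); IJA1: (target->face - non-target->face)/(sum); empty for IJA2 |
| fd_pct_face / fd_pct_target / fd_pct_non_target | JA-phase fixation time on the AOI as % of all JA-phase fixation time over usable trials |
| fd_pct_*_first_target | the same restricted to trials with a congruent (target) first look |

## group_comparisons.csv
One row per tested variable and task.

| column | meaning |
|---|---|
| task, variable | what is compared |
| mean_ASD, sd_ASD, mean_TD, sd_TD | raw group statistics |
| F, df1, df2, p | group term of dv ~ group + covariate |
| eta2_partial | SS_group / (SS_group + SS_residual) |
| ranked | TRUE when the Shapiro-Wilk gate sent the variable to the rank ANCOVA |
| levene_p | Levene's test (mean-centred) on the analysed dv |
| fdr_significant | Benjamini-Hochberg decision at q = 0.05 within the task family |

## usable_trials.csv / usable_trials_by_group.csv
Per-participant usable-trial counts (overall and per task) and the group
mean/sd of the overall count.

## usable_trials_anova.csv
Repeated-measures ANOVA on usable-trial counts: task (within), group:task,
and group (between) terms with F, dfs, p.

## fd_summary.csv
Group mean and sd of every fixation-duration percentage per task.

## correlations.csv
Cross-task correlations of comparable transition rates (IJA1 vs IJA2)
within each group, with the chosen method (pearson/spearman) and n.

## manifest.json
Package version, seed, participant count, analysis options, excluded-trial
counts by reason, and an echo of the study configuration.
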