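#!/usr/bin/env Rscript
# Step 4 - resting-state connectivity.
# Two groups of nine 120-point resting runs realise prescribed ROI
# correlation structures over the eight-region layout. The groups share
# strong interhemispheric homologue coupling; they differ only in the sign
# of the V1-MT+ coupling (positive in the "infant-like" group, negative in
# the "adult-like" one). The analysis computes per-subject matrices,
# group means, super-subject significance, and the cell-wise two-group
# t-test that should single out the V1-MT+ cells.

suppressPackageStartupMessages(library(flowbold))
dir.create("results", showWarnings = FALSE)

lay <- default_layout("coh_vs_random")
labels <- names(lay$regions)
k <- length(labels)

base_target <- function(v1mt) {
  M <- diag(k)
  dimnames(M) <- list(labels, labels)
  pairs <- list(c("V1_L", "V1_R"), c("MT_L", "MT_R"), c("PIVC_L", "PIVC_R"))
  for (p in pairs) M[p[1], p[2]] <- M[p[2], p[1]] <- 0.6
  assoc <- list(c("V6", "PCuCu"), c("V6", "MT_L"), c("V6", "MT_R"))
  for (p in assoc) M[p[1], p[2]] <- M[p[2], p[1]] <- 0.4
  for (p in list(c("V1_L", "MT_L"), c("V1_L", "MT_R"),
                 c("V1_R", "MT_L"), c("V1_R", "MT_R")))
    M[p[1], p[2]] <- M[p[2], p[1]] <- v1mt
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  stopifnot(min(ev) > 0)
  M
}

acq <- acquisition_spec("rest")
rois <- lapply(lay$regions, function(r) r$voxels)
ns <- noise_spec(0.3, 0, 0)

group_matrices <- function(v1mt, seed0) {
  tgt <- base_target(v1mt)
  lapply(1:9, function(s) {
    run <- simulate_rest_run(lay, tgt, acq, ns, seed = seed0 + s)
    roi_correlation_matrix(run, rois)
  })
}

infants <- group_matrices(+0.45, 4100)
adults <- group_matrices(-0.45, 4200)

ss_inf <- supersubject_significance(lapply(infants, attr, "series"))
ss_adu <- supersubject_significance(lapply(adults, attr, "series"))
cmp <- compare_group_matrices(infants, adults)

write_matrix_tsv(round(cmp$mean_a, 3), "results/connectivity_infantlike.tsv")
write_matrix_tsv(round(cmp$mean_b, 3), "results/connectivity_adultlike.tsv")
write_json_file(list(
  supersubject_p_infantlike = ss_inf$p,
  supersubject_p_adultlike = ss_adu$p,
  group_difference_t = cmp$t, group_difference_p = cmp$p,
  tiers = cmp$tier
), "results/connectivity_tests.json")

cat("group-mean V1_L-MT_L correlation: infant-like",
    sprintf("%+.2f,", cmp$mean_a["V1_L", "MT_L"]),
    "adult-like", sprintf("%+.2f\n", cmp$mean_b["V1_L", "MT_L"]))
flagged <- which(cmp$tier != "" & upper.tri(cmp$tier), arr.ind = TRUE)
cat("cells differing between groups:\n")
for (i in seq_len(nrow(flagged)))
  cat(sprintf("  %s - %s: t = %+.2f, %s\n",
              labels[flagged[i, 1]], labels[flagged[i, 2]],
              cmp$t[flagged[i, 1], flagged[i, 2]],
              cmp$tier[flagged[i, 1], flagged[i, 2]]))
n_sig <- sum(ss_inf$p < 0.05 & upper.tri(ss_inf$p))
cat(sprintf("super-subject: %d of %d infant-like cells significant at p<0.05\n",
            n_sig, k * (k - 1) / 2))
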