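#!/usr/bin/env Rscript
# Step 2: fit the two-stage ORN encoder from synthetic sensillum trials.
#
# Six 60-s stimulus patterns (smoothed border-crossing profiles spanning
# the arena's intensity range) are played through the ground-truth
# encoder at signal-to-noise 10, and the stimulus -> LFP -> firing-rate
# cascade is re-fit by ridge regression with L-curve selection of the
# regularization strength.  The fitted cascade is serialized for the
# mapping and simulation steps.

suppressPackageStartupMessages(library(odorwalk))
dir.create("results", showWarnings = FALSE)

truth <- make_ground_truth(seed = 1)
set.seed(21)
mk_pattern <- function(n = 6000, plateau = 20) {
  x <- as.numeric(stats::filter(stats::runif(n), rep(1 / 300, 300),
                                sides = 1))
  x[is.na(x)] <- x[which(!is.na(x))[1]]
  z <- (x - mean(x)) / stats::sd(x)
  plateau * pmin(pmax(z * 0.7 + 0.5, 0), 1)
}
patterns <- replicate(6, mk_pattern(), simplify = FALSE)
clean <- generate_ephys_trials(truth, patterns[1],
                               noise_sd = list(lfp = 0, rate = 0))[[1]]
noise <- list(lfp = stats::sd(clean$lfp) / sqrt(10),
              rate = stats::sd(clean$rate - 4.7) / sqrt(10))
trials <- generate_ephys_trials(truth, patterns, noise_sd = noise,
                                seed = 22)

cascade <- fit_cascade(lapply(trials, `[[`, "stimulus"),
                       lapply(trials, `[[`, "lfp"),
                       lapply(trials, `[[`, "rate"), baseline = 4.7)
write_cascade(cascade, "results/cascade.json")

nrmse <- function(est, tru) {
  L <- max(length(est), length(tru))
  sqrt(mean((c(est, rep(0, L - length(est))) -
               c(tru, rep(0, L - length(tru))))^2)) / diff(range(tru))
}
hold <- generate_ephys_trials(truth, list(mk_pattern()),
                              noise_sd = list(lfp = 0, rate = 0),
                              seed = 23)[[1]]
pred <- predict_response(cascade, hold$stimulus)
r2 <- 1 - sum((pred$rate - hold$rate)^2) /
  sum((hold$rate - mean(hold$rate))^2)
tab <- data.frame(
  quantity = c("stage1_nrmse", "stage2_nrmse", "holdout_r2",
               "lambda1", "lambda2"),
  value = c(nrmse(cascade$filter1, truth$encoder$filter1),
            nrmse(cascade$filter2, truth$encoder$filter2), r2,
            cascade$fits$stage1$lambda_star,
            cascade$fits$stage2$lambda_star))
utils::write.csv(tab, "results/encoder_fit.csv", row.names = FALSE)
cat(sprintf("Cascade recovered: stage-1 NRMSE %.3f, stage-2 NRMSE %.3f, held-out R^2 %.3f.\n",
            tab$value[1], tab$value[2], tab$value[3]))
cat("Wrote results/cascade.json and results/encoder_fit.csv\n")
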