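#!/usr/bin/env Rscript

# Step 5 — figures from the sweep table written by 04_scenario_sweep.R.
# Phenology panels (nesting onset, clutch size, recruitment probability
# against spring onset) and the recruitment panels (variance and relative
# mean recruits against food-gain variance).

library(ggplot2)

tab <- read.csv("results/scenario_table.csv")
tab$env <- factor(ifelse(is.na(tab$alpha), "constant",
                         sprintf("alpha %g", tab$alpha)),
                  levels = c("constant", sprintf("alpha %g",
                                                 sort(unique(tab$alpha),
                                                      decreasing = TRUE))))
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

long <- rbind(
  data.frame(tab, panel = "nesting onset (days after b_s)",
             y = tab$onset_rel_bs),
  data.frame(tab, panel = "clutch size (eggs)", y = tab$clutch_mean),
  data.frame(tab, panel = "recruitment probability", y = tab$recruit_prob))
ggsave("results/figures/phenology_vs_spring_onset.pdf",
       ggplot(long, aes(b_s, y, colour = env)) +
         geom_line() + geom_point(size = 1) +
         facet_grid(panel ~ strategy, scales = "free_y") +
         labs(x = "first possible breeding day b_s", y = NULL,
              colour = "food gain") + theme_bw(),
       width = 8, height = 8)

st <- tab[!is.na(tab$alpha), ]
st$log_alpha <- log10(st$alpha)
rec <- rbind(
  data.frame(st, panel = "variance in recruits", y = st$recruits_var),
  data.frame(st, panel = "recruits relative to constant food",
             y = st$rel_recruitment))
ggsave("results/figures/recruitment_vs_variance.pdf",
       ggplot(rec, aes(-log_alpha, y, colour = factor(b_s))) +
         geom_hline(data = data.frame(
           panel = "recruits relative to constant food", h = 1),
           aes(yintercept = h), linetype = 2, colour = "grey50") +
         geom_line() + geom_point(size = 1) +
         facet_grid(panel ~ strategy, scales = "free_y") +
         labs(x = "food-gain variance (-log10 alpha)", y = NULL,
              colour = "b_s") + theme_bw(),
       width = 8, height = 6)
cat("Written: results/figures/*.pdf\n")
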