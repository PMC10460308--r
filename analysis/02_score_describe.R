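#!/usr/bin/env Rscript
# Score WHO-ASSIST involvement, dichotomise use/harm indicators, assign the
# high-centrality substance groups and produce the descriptive comparison
# table (overall + three use groups, chi-square / Kruskal-Wallis p-values).
# Also recomputes the published descriptive prevalences from the bundled
# printed counts as a cross-reference.

suppressPackageStartupMessages(library(assistnet))

cohort <- read_cohort("results/cohort.csv")
scores <- involvement_scores(cohort)
ind <- dichotomize_items(cohort)
groups <- assign_group(ind)

write.csv(cbind(participant_id = cohort$participant_id, scores,
                group = as.character(groups)),
          "results/involvement_scores.csv", row.names = FALSE)

dat <- cbind(cohort, ind,
             use_group = factor(groups, levels = c("alcohol_tobacco_other",
                                                   "cannabis_no_ats", "ats")))
dat$n_substances <- rowSums(
  as.matrix(ind[paste0(assist_substances(), "_used")]))
vars <- c(paste0(assist_substances(), "_used"), "n_substances",
          "any_urge", "any_problems", "any_failed_expect", "any_concerns")
tab <- describe_by_group(dat, vars, "use_group")
write.csv(tab, "results/descriptives_by_group.csv", row.names = FALSE)

cat("Group sizes:",
    paste(names(table(groups)), table(groups), sep = "=", collapse = ", "),
    "(", sum(is.na(groups)), "unresolved )\n")
cat("Descriptive table written to results/descriptives_by_group.csv\n")

counts <- read.csv(system.file("extdata", "published_counts.csv",
                               package = "assistnet"))
counts$denominator <- suppressWarnings(as.numeric(counts$denominator))
prev <- prevalence_from_counts(counts, cohort_n = 1107)
write.csv(prev[c("measure", "numerator", "denominator", "percent")],
          "results/published_prevalences.csv", row.names = FALSE)
cat("Published-count prevalences (percent):\n")
print(setNames(round(prev$percent, 1), prev$measure))
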