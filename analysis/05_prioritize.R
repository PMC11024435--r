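#!/usr/bin/env Rscript
# The selection cascade: non-toxic inhibitors with IC50 <= 5 ug/mL, then
# SC = 1, then < 10 literature reports at species and genus, then CC = 1;
# the survivors ranked by Priority Score. Compares the shortlist with the
# scenario's planted truth.

suppressMessages(library(extractprio))

scenario <- read_scenario("results/scenario")
calls <- read.delim("results/activity_calls.tsv")
scores <- read.delim("results/component_scores.tsv")

report <- run_cascade(calls, scores, scenario$taxa)
print(report)
write.table(report$shortlist, "results/shortlist.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cascade_report_json(report, "results/funnel.json")

truth <- jsonlite::read_json(file.path("results/scenario", "truth.json"),
                             simplifyVector = TRUE)
planted <- sort(truth$extract_id[truth$survivor])
final <- report$shortlist$extract_id
cat("\nplanted survivors:   ", paste(planted, collapse = ", "), "\n")
cat("recovered shortlist: ", paste(final, collapse = ", "), "\n")
cat(sum(planted %in% final), "of", length(planted),
    "planted survivors recovered\n")
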