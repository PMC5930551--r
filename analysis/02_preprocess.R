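#!/usr/bin/env Rscript
# Motion-aware temporal preprocessing: band-pass 0.008-0.1 Hz, nuisance
# regression (6 motion parameters + global signal), FD scrubbing at
# 0.5 mm (-1/+2 window), DVARS-based subject exclusion. Writes the
# per-subject QC table.

source("analysis/00_config.R")

cohort <- build_cohort()
pp <- preprocess_cohort(cohort)

write_tsv(pp$qc, "qc_table.tsv")
message(sprintf("retained frames: mean %.1f%% (range %.1f-%.1f%%)",
                100 * mean(pp$qc$retained_fraction),
                100 * min(pp$qc$retained_fraction),
                100 * max(pp$qc$retained_fraction)))
message("subjects excluded by the 3-IQR DVARS rule: ",
        sum(pp$qc$excluded_flag))
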