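#!/usr/bin/env Rscript
# SNP quality control and genome-wide relatedness. Filters follow the
# field-standard GBS pipeline order (locus call rate 90%, MAF > 0.01,
# individual call rate 85%, oHET within 2-98%), then mean-dosage
# imputation and the VanRaden method-1 GRM with a ridge stabilization for
# later inversion.
library(wildqg)

ph <- as.data.frame(data.table::fread("results/study/phenotypes.csv"))
g <- read_genotypes("results/study/genotypes.tsv",
                    sites = unique(ph[c("plant_id", "site")]))

qc <- apply_qc_filters(g)
rep <- attr(qc, "qc_report")
cat(sprintf("QC: %d -> %d loci (call rate %d, MAF %d, oHET %d removed); %d -> %d individuals\n",
            rep$input$loci, rep$output$loci, rep$loci_removed_call_rate,
            rep$loci_removed_maf, rep$loci_removed_ohet,
            rep$input$individuals, rep$output$individuals))

G <- stabilize_for_inversion(vanraden_grm(impute_missing(qc)))
s <- relatedness_summary(G, qc$sites)
cat(sprintf("GRM: %d loci; off-diagonals %.2f to %.2f, %.0f%% below 0.2; ridge %.1e\n",
            G$n_loci_used, s$off$min, s$off$max,
            100 * s$off$frac_below_0.2, G$ridge_applied))

dir.create("results", showWarnings = FALSE)
write_grm(G, "results/grm.tsv")
jsonlite::write_json(c(rep, s["off"]), "results/qc_grm.json",
                     auto_unbox = TRUE, digits = NA, force = TRUE)
cat("GRM written to results/grm.tsv\n")
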