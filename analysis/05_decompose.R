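#!/usr/bin/env Rscript
# Decompose the fitted per-site binding free energies into hydration,
# specific-interaction and rotational/translational-plus-conformational
# contributions.

library(quadlink)

fitted <- read.csv("results/fit_binding.csv")
est <- setNames(fitted$estimate, fitted$parameter)
sites <- list(site_thermo(1, est[["s1.dG0"]], est[["s1.dH0"]], est[["s1.dCp"]]),
              site_thermo(2, est[["s2.dG0"]], est[["s2.dH0"]], est[["s2.dCp"]]))

tab <- do.call(rbind, lapply(sites, function(s) {
  d <- decompose_binding(s)
  data.frame(site = d$site, Gtotal = d$Gtotal, Ghyd = d$Ghyd,
             Gint = d$Gint, Gother = d$Gother)
}))
write.csv(tab, "results/energy_decomposition.csv", row.names = FALSE)
print(tab, digits = 3, row.names = FALSE)

cat("\nSite 1 (upper end, intermediate only): interaction-driven, little\n")
cat("dehydration.  Site 2 (bottom end, shared by Q and I): strongly\n")
cat("hydration- and interaction-driven, paid for by a large unfavorable\n")
cat("conformational/rigid-body term.\n")
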