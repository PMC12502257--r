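# Regenerates the bundled catalog files under inst/extdata/ from the
# builders in R/reference_build.R. Run from the package root:
#   Rscript data-raw/build_reference_catalogs.R
pkgload::load_all(".", quiet = TRUE)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write_catalog(build_vmra_reference(), "inst/extdata/vmra_reference.yaml")
write_catalog(build_who_skeleton(), "inst/extdata/who_gbt_skeleton.yaml")
cat("wrote inst/extdata/vmra_reference.yaml and inst/extdata/who_gbt_skeleton.yaml\n")
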