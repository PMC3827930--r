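# Regenerates the packaged synthetic reference-panel fixtures under
# inst/extdata/ from generate_reference_panel() with its default seed.
# Run from the repository root: Rscript scripts/make_panel_fixtures.R
suppressMessages(pkgload::load_all(".", quiet = TRUE))

sp <- generate_reference_panel()
write_proteins(sp$records, "inst/extdata/synthetic_reference_panel.fasta")
an <- sp$lip3_annotation
jsonlite::write_json(list(id = an$id, sequence = an$sequence,
                          gggf_start = an$gggf_start,
                          gesag_start = an$gesag_start,
                          ser = an$ser, glu = an$glu, his = an$his,
                          cys = an$cys, note = an$note),
                     "inst/extdata/lip3_synthetic_annotation.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)
cat("fixtures written\n")
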