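# shared wiring from a written funnel bundle to a run configuration
bundle_acceptance_config <- function(paths, dir) {
  funnel_config(proteome_fasta = paths[["proteome"]],
                screen_files = unname(paths[c("screen1", "screen2",
                                              "screen3")]),
                alias_file = paths[["aliases"]],
                annotation_file = paths[["annotations"]],
                regulon_file = paths[["regulon"]],
                promoter_fasta = paths[["promoters"]],
                out_dir = file.path(dir, "out"))
}
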