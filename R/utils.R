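# internal helpers shared across modules

# evaluate expr under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# derive a per-stage seed from a run seed; keeps results of one stage stable
# when other stages are added or re-ordered; stays inside 32-bit range
substream_seed <- function(seed, stage) {
  stage_id <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + stage_id) %% 2147483629)
}

# round half away from zero (platform-stable, unlike IEEE round-half-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# TSV + sidecar JSON writer used by the pipeline outputs
write_tsv_with_meta <- function(df, file, meta = NULL) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  if (!is.null(meta)) {
    meta$package_version <- as.character(utils::packageVersion("traitspacer"))
    jsonlite::write_json(meta, paste0(file, ".meta.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(file)
}
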