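# Plain-text session serialization: spike times, LFP, behavior and a config
# echo round-trip through one directory.

#' Write a session to a directory
#'
#' Layout: \code{spikes.csv} (unit, region, time), \code{behavior.csv},
#' one \code{lfp_<REGION>.csv} per region with an \code{lfp_meta.json}
#' sidecar (sample rate, start time), and \code{config.json} echoing the
#' generator configuration. Ground truth is not serialized (it is a property
#' of the generator, not of recorded data).
#'
#' @param session a [SyntheticSession-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSession <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- session@spikes
  spikes_df <- data.frame(
    unit = rep(sp@unitIds, lengths(sp@times)),
    region = rep(sp@region, lengths(sp@times)),
    time = unlist(sp@times, use.names = FALSE))
  utils::write.csv(spikes_df, file.path(dir, "spikes.csv"),
                   row.names = FALSE)
  utils::write.csv(session@behavior, file.path(dir, "behavior.csv"),
                   row.names = FALSE)
  meta <- list(units = data.frame(unit = sp@unitIds, region = sp@region))
  lfp_meta <- list()
  for (rg in names(session@lfp)) {
    tr <- session@lfp[[rg]]
    utils::write.csv(data.frame(sample = tr@samples),
                     file.path(dir, paste0("lfp_", rg, ".csv")),
                     row.names = FALSE)
    lfp_meta[[rg]] <- list(fs = tr@fs, t0 = tr@t0)
  }
  jsonlite::write_json(lfp_meta, file.path(dir, "lfp_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(configParams(session@config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session directory
#'
#' @param dir directory written by [writeSession()].
#' @return list with \code{spikes} ([SpikeSet-class]), \code{lfp} (named list
#'   of [LfpTrace-class]), \code{behavior} (data.frame) and \code{config}
#'   ([SynthConfig-class]).
#' @export
readSession <- function(dir) {
  spikes_df <- utils::read.csv(file.path(dir, "spikes.csv"),
                               stringsAsFactors = FALSE)
  units <- unique(spikes_df[, c("unit", "region")])
  spikes <- SpikeSet(
    times = lapply(units$unit, function(u)
      spikes_df$time[spikes_df$unit == u]),
    unitIds = units$unit, region = units$region)
  behavior <- utils::read.csv(file.path(dir, "behavior.csv"),
                              stringsAsFactors = FALSE)
  lfp <- list()
  meta_path <- file.path(dir, "lfp_meta.json")
  if (file.exists(meta_path)) {
    lfp_meta <- jsonlite::read_json(meta_path)
    for (rg in names(lfp_meta)) {
      samples <- utils::read.csv(file.path(dir, paste0("lfp_", rg,
                                                       ".csv")))$sample
      lfp[[rg]] <- LfpTrace(samples, lfp_meta[[rg]]$fs, rg,
                            lfp_meta[[rg]]$t0 %||% 0)
    }
  }
  pj <- jsonlite::read_json(file.path(dir, "config.json"),
                            simplifyVector = TRUE, simplifyDataFrame = FALSE)
  pj$behavior_coupling <- lapply(pj$behavior_coupling, function(bc)
    list(var = bc$var, latent = bc$latent, strength = bc$strength))
  cfg <- do.call(synthConfig, pj[names(pj) %in%
                                   names(formals(synthConfig))])
  list(spikes = spikes, lfp = lfp, behavior = behavior, config = cfg)
}

#' Write a WindowSet to a BED-like interval file
#'
#' Three tab-separated columns (start, stop, label) on a seconds axis with
#' half-open \code{[start, stop)} semantics.
#'
#' @param ws a [WindowSet-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeWindows <- function(ws, path) {
  utils::write.table(
    data.frame(start = ws@start, stop = ws@stop,
               label = paste(ws@state, ws@level, sep = ".")),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a WindowSet interval file
#' @param path file written by [writeWindows()].
#' @return a [WindowSet-class].
#' @export
readWindows <- function(path) {
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("start", "stop", "label"))
  lab <- strsplit(df$label[1], ".", fixed = TRUE)[[1]]
  WindowSet(df$start, df$stop, lab[1], lab[2])
}
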