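#' Chunked on-disk store for a processed corpus
#'
#' A processed corpus (patch tensors, padding information, labels,
#' positivity and metadata) is written as a hierarchical directory store:
#' `datasets/<id>/{patches.bin, meta.json, cells.csv, positivity.csv}`,
#' one chunk per dataset, with patch tensors as raw little-endian doubles.
#' Reading the store back reproduces the in-memory corpus bit-exactly.
#'
#' @param corpus a `phenoclip_corpus` (see [make_corpus()]).
#' @param path directory to create.
#' @return `path`, invisibly; `read_corpus_store()` returns the corpus.
#' @export
write_corpus_store <- function(corpus, path) {
  dir.create(file.path(path, "datasets"), recursive = TRUE,
             showWarnings = FALSE)
  ds_ids <- names(corpus$panels)
  for (id in ds_ids) {
    dd <- file.path(path, "datasets", id)
    dir.create(dd, showWarnings = FALSE)
    sel <- corpus$cells$dataset_id == id
    cells <- corpus$cells[sel, , drop = FALSE]
    C <- length(corpus$panels[[id]])
    con <- file(file.path(dd, "patches.bin"), "wb")
    for (i in which(sel)) {
      off <- corpus$cells$offset[i]
      n <- corpus$cells$n_channels[i] * 12288
      writeBin(corpus$patch_data[(off + 1):(off + n)], con, size = 8,
               endian = "little")
    }
    close(con)
    jsonlite::write_json(
      list(panel = corpus$panels[[id]], n_cells = nrow(cells),
           patch_shape = c(64L, 64L, 3L, C)),
      file.path(dd, "meta.json"), auto_unbox = TRUE)
    write.csv(cells[, setdiff(names(cells), "offset")],
              file.path(dd, "cells.csv"), row.names = FALSE)
    pos <- corpus$positivity[sel, seq_len(C), drop = FALSE]
    colnames(pos) <- corpus$panels[[id]]
    write.csv(cbind(cell_id = cells$cell_id, as.data.frame(pos)),
              file.path(dd, "positivity.csv"), row.names = FALSE)
  }
  jsonlite::write_json(list(datasets = ds_ids, types = corpus$types,
                            modalities = corpus$modalities),
                       file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_corpus_store
#' @export
read_corpus_store <- function(path) {
  top <- jsonlite::read_json(file.path(path, "meta.json"),
                             simplifyVector = TRUE)
  panels <- list()
  cells_all <- NULL
  patch_chunks <- list()
  pos_all <- list()
  max_C <- 0L
  for (id in top$datasets) {
    dd <- file.path(path, "datasets", id)
    meta <- jsonlite::read_json(file.path(dd, "meta.json"),
                                simplifyVector = TRUE)
    panels[[id]] <- meta$panel
    cells <- read.csv(file.path(dd, "cells.csv"), stringsAsFactors = FALSE)
    n <- meta$n_cells
    C <- length(meta$panel)
    max_C <- max(max_C, C)
    con <- file(file.path(dd, "patches.bin"), "rb")
    patch_chunks[[id]] <- readBin(con, "double", n * C * 12288, size = 8,
                                  endian = "little")
    close(con)
    pos <- read.csv(file.path(dd, "positivity.csv"))
    pos_all[[id]] <- as.matrix(pos[, -1, drop = FALSE])
    cells_all <- rbind(cells_all, cells)
  }
  patch_data <- unlist(patch_chunks, use.names = FALSE)
  # recompute offsets in concatenation order (datasets in meta order)
  offs <- numeric(nrow(cells_all))
  cur <- 0
  k <- 1L
  for (id in top$datasets) {
    C <- length(panels[[id]])
    n <- sum(cells_all$dataset_id == id)
    for (i in seq_len(n)) {
      offs[k] <- cur
      cur <- cur + C * 12288
      k <- k + 1L
    }
  }
  cells_all$offset <- offs
  pos <- matrix(NA_real_, nrow(cells_all), max_C)
  r <- 1L
  for (id in top$datasets) {
    m <- pos_all[[id]]
    pos[r:(r + nrow(m) - 1L), seq_len(ncol(m))] <- m
    r <- r + nrow(m)
  }
  structure(list(patch_data = patch_data, cells = cells_all,
                 panels = panels, positivity = pos,
                 types = top$types, modalities = top$modalities),
            class = "phenoclip_corpus")
}
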