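# Synthetic labeled corpora with the statistical structure the classifier
# pipeline assumes: three topic classes at realistic forum proportions,
# class-signature n-gram phrases, medical domain-term injection (heaviest
# in the treatment-like class), and sentiment-term injection (heaviest in
# the emotional-support-like class).  Token emission is an i.i.d. mixture
# over emission units (a unit is a word or a multiword phrase emitted
# atomically), which keeps a closed-form Bayes-optimal reference classifier
# available for parameter-recovery tests.

.sig_pools <- list(
  treatment = c("chemo cycle", "taxol", "herceptin", "infusion day",
                "radiation boost", "port flush", "dose dense", "neulasta shot",
                "oncologist visit", "lumpectomy margins", "ac regimen",
                "taxotere", "scan results", "white counts", "pre meds"),
  emotional = c("gentle hugs", "prayers going up", "warm thoughts",
                "hang in there", "big hug", "thinking of you", "candle lit",
                "virtual hug", "sending love", "stay strong", "god bless",
                "well wishes", "kind words", "heart goes out", "cheering for you"),
  survivorship = c("five years out", "new normal", "survivor walk",
                   "anniversary date", "moving forward", "post treatment life",
                   "follow up visit", "back to work", "daily routine",
                   "long term", "life after", "celebrate milestones",
                   "yearly mammo", "getting stronger", "fresh start"))

.dom_pools <- list(
  treatment = c("chemotherapy", "mastectomy", "tamoxifen", "radiation therapy",
                "biopsy", "anemia", "neutropenia", "neuropathy", "nausea",
                "estrogen", "carcinoma", "metastasis", "bone scan",
                "blood count", "tumor marker", "aromatase inhibitor",
                "lymph node", "reconstruction", "anesthesia", "ultrasound"),
  emotional = c("depression", "anxiety", "insomnia", "fatigue",
                "panic disorder", "stress reaction", "grief reaction",
                "mood swing", "appetite loss", "migraine"),
  survivorship = c("lymphedema", "osteoporosis", "menopause", "hot flash",
                   "joint pain", "memory loss", "weight gain", "hypertension",
                   "mammogram", "bone density", "thyroid", "cholesterol",
                   "physical therapy", "hormone therapy", "vitamin d"))

.sent_pools <- list(
  treatment = c("worried", "tired", "relieved", "nervous", "brave"),
  emotional = c("hopeful", "grateful", "scared", "love", "comfort",
                "blessed", "strength", "courage", "tears", "joy",
                "caring", "sweet", "lonely", "afraid", "wonderful"),
  survivorship = c("thankful", "proud", "happy", "confident", "peaceful",
                   "optimistic", "alive", "free"))

.distractor_lemmas <- c("morning", "window", "report", "coffee", "garden",
                        "weather", "kitchen", "travel", "paper", "music")

.shared_base <- c("week", "time", "day", "doctor", "appointment", "family",
                  "home", "work", "friend", "question", "board", "post",
                  "thread", "everyone", "today", "year", "month", "news",
                  "side", "thing")

.stop_units <- c("i", "the", "and", "a", "to", "of", "it", "was", "my", "so")

# extend a base pool to `size` entries with numbered synthetic variants
.extend_pool <- function(base, size, tag) {
  if (size <= length(base)) return(base[seq_len(size)])
  extra <- sprintf("%s%03d", tag, seq_len(size - length(base)))
  c(base, extra)
}

#' Configure the synthetic corpus generator
#'
#' The default preset emulates a three-topic breast-cancer forum corpus:
#' 4,041 messages at class proportions 1224 : 991 : 1826
#' (treatment : emotional : survivorship), mean message length 30 emission
#' units for every class (equal lengths keep message length uninformative),
#' per-class signature phrases carrying n-gram signal, domain-term
#' injection heaviest in the treatment class, and sentiment-term injection
#' heaviest in the emotional-support class.
#'
#' Presets:
#' \describe{
#'   \item{`"default"`}{the study conditions above.}
#'   \item{`"strong"`}{doubled signature weight -- a strongly separable
#'     corpus whose Bayes-optimal accuracy exceeds 0.97, used for
#'     classifier sanity properties.}
#'   \item{`"domain_signal"`}{no signature phrases and no sentiment signal;
#'     all class signal rides on *individually rare* domain terms (large
#'     per-class term pools), so an n-gram frequency threshold of 20
#'     excludes them from FS1 while the domain lexicon recovers them in
#'     FS2.  Used to demonstrate the FS1-vs-FS2 comparison protocol.}
#' }
#'
#' @param preset `"default"`, `"strong"` or `"domain_signal"`.
#' @param n_messages corpus size (default 4041).
#' @param seed generator seed.
#' @param class_proportions numeric simplex (normalized if needed) over the
#'   three classes.
#' @param length_mean per-class Poisson mean of the number of emission
#'   units per message.
#' @param shared_vocab_size size of the class-neutral filler vocabulary.
#' @param signature_weight per-class probability that a unit is a
#'   signature phrase.
#' @param domain_rate per-class probability that a unit is a medical
#'   domain term.
#' @param sentiment_rate per-class probability that a unit is a sentiment
#'   lemma.
#' @param domain_pool_size per-class number of domain terms (base lists
#'   are extended with synthetic numbered terms when larger).
#' @param stop_rate probability of emitting a stop word (class-neutral).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(preset = c("default", "strong", "domain_signal"),
                         n_messages = 4041, seed = 20130710,
                         class_proportions = c(1224, 991, 1826),
                         length_mean = c(30, 30, 30),
                         shared_vocab_size = 300,
                         signature_weight = NULL,
                         domain_rate = NULL,
                         sentiment_rate = NULL,
                         domain_pool_size = NULL,
                         stop_rate = 0.15) {
  preset <- match.arg(preset)
  classes <- c("treatment", "emotional", "survivorship")
  if (any(class_proportions < 0) || sum(class_proportions) <= 0) {
    stop("class proportions must be a non-negative non-degenerate simplex")
  }
  props <- class_proportions / sum(class_proportions)
  defaults <- switch(preset,
    default = list(signature_weight = c(0.06, 0.06, 0.06),
                   domain_rate = c(0.10, 0.02, 0.05),
                   sentiment_rate = c(0.02, 0.10, 0.04),
                   domain_pool_size = c(20, 10, 15)),
    strong = list(signature_weight = c(0.12, 0.12, 0.12),
                  domain_rate = c(0.10, 0.02, 0.05),
                  sentiment_rate = c(0.02, 0.10, 0.04),
                  domain_pool_size = c(20, 10, 15)),
    domain_signal = list(signature_weight = c(0, 0, 0),
                         domain_rate = c(0.15, 0.06, 0.10),
                         sentiment_rate = c(0, 0, 0),
                         domain_pool_size = c(120, 120, 120)))
  if (is.null(signature_weight)) signature_weight <- defaults$signature_weight
  if (is.null(domain_rate)) domain_rate <- defaults$domain_rate
  if (is.null(sentiment_rate)) sentiment_rate <- defaults$sentiment_rate
  if (is.null(domain_pool_size)) domain_pool_size <- defaults$domain_pool_size
  rates <- rbind(signature_weight, domain_rate, sentiment_rate)
  if (any(rates < 0) || any(rates > 1)) stop("rates must lie in [0, 1]")
  if (any(colSums(rates) + stop_rate >= 1)) {
    stop("per-class signature + domain + sentiment + stop rates must leave room for shared vocabulary")
  }
  pools <- list(
    shared = sprintf("filler%03d", seq_len(shared_vocab_size)),
    stop = .stop_units,
    signature = .sig_pools,
    domain = Map(function(base, size, tag) .extend_pool(base, size, tag),
                 .dom_pools, as.list(domain_pool_size),
                 list("medterm", "symptomx", "latecond")),
    sentiment = .sent_pools)
  structure(list(preset = preset, n_messages = as.integer(n_messages),
                 classes = classes, class_proportions = props,
                 length_mean = length_mean,
                 signature_weight = signature_weight,
                 domain_rate = domain_rate, sentiment_rate = sentiment_rate,
                 stop_rate = stop_rate, pools = pools, seed = seed),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> preset '%s': %d messages, proportions %s (seed %s)\n",
              x$preset, x$n_messages,
              paste(sprintf("%.3f", x$class_proportions), collapse = ":"),
              format(x$seed)))
  invisible(x)
}

# per-class emission distribution over categories
.cat_probs <- function(config, j) {
  w <- c(signature = config$signature_weight[j],
         domain = config$domain_rate[j],
         sentiment = config$sentiment_rate[j],
         stop = config$stop_rate)
  c(w, shared = 1 - sum(w))
}

.class_pools <- function(config, j) {
  cl <- config$classes[j]
  list(signature = config$pools$signature[[cl]],
       domain = config$pools$domain[[cl]],
       sentiment = config$pools$sentiment[[cl]],
       stop = config$pools$stop,
       shared = config$pools$shared)
}

.emit_units <- function(config, j, L) {
  if (L == 0) return(character())
  probs <- .cat_probs(config, j)
  pools <- .class_pools(config, j)
  cats <- sample(names(probs), L, replace = TRUE, prob = probs)
  units <- character(L)
  for (cat in unique(cats)) {
    rows <- cats == cat
    units[rows] <- sample(pools[[cat]], sum(rows), replace = TRUE)
  }
  units
}

#' Generate a synthetic labeled corpus
#'
#' For each message: class drawn from the configured proportions, length
#' (number of emission units) from the class Poisson, units i.i.d. from
#' the class mixture of shared vocabulary, signature phrases, domain
#' terms, sentiment lemmas and stop words.  Multiword phrases are emitted
#' atomically, creating genuine n-gram signal.  Fully reproducible under
#' the config seed.
#'
#' @param config a [synth_config()].
#' @return A list with `corpus` (a fully labeled `topic_corpus`) and
#'   `config` (the ground-truth generative parameters, echoed back for
#'   oracle computations).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_messages
  corp <- local_seed(config$seed, {
    cls_idx <- sample.int(length(config$classes), n, replace = TRUE,
                          prob = config$class_proportions)
    texts <- character(n)
    for (d in seq_len(n)) {
      j <- cls_idx[d]
      L <- stats::rpois(1, config$length_mean[j])
      texts[d] <- paste(.emit_units(config, j, L), collapse = " ")
    }
    corpus(data.frame(id = sprintf("msg%05d", seq_len(n)),
                      text = texts,
                      label = config$classes[cls_idx],
                      stringsAsFactors = FALSE))
  })
  list(corpus = corp, config = config)
}

#' Generate lexicon files matching a synthetic corpus
#'
#' Writes (and loads back) a domain lexicon TSV covering exactly the
#' config's domain terms, labeled with health-related semantic-type codes,
#' and a SentiWordNet-format sentiment lexicon in which every injected
#' sentiment lemma has subjectivity above 0.5 (so all pass the default
#' filter) plus distractor lemmas with subjectivity at most 0.5.  A few
#' lemmas carry two senses to exercise sense aggregation.  Both files are
#' round-trippable through [load_domain_lexicon()] /
#' [load_sentiment_lexicon()] by construction (the returned objects *are*
#' loaded from the written files).
#'
#' @param config a [synth_config()].
#' @param dir output directory (default: a session temp directory).
#' @return A list with `domain` (a `domain_lexicon`), `sentiment` (a
#'   `sentiment_lexicon`), and `paths`.
#' @export
generate_lexicons <- function(config, dir = tempfile("synthlex")) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  codes_by_class <- list(
    treatment = c("Topp", "Phsu", "Diap", "Horm", "Neop", "Sosy"),
    emotional = c("Mobd", "Sosy", "Patf"),
    survivorship = c("Dsyn", "Sosy", "Patf", "Diap", "Bpoc"))
  dom_lines <- c("# synthetic domain lexicon (term<TAB>semantic-type code)")
  for (cl in config$classes) {
    terms <- config$pools$domain[[cl]]
    codes <- rep_len(codes_by_class[[cl]], length(terms))
    dom_lines <- c(dom_lines, paste(terms, codes, sep = "\t"))
  }
  dom_path <- file.path(dir, "domain_lexicon.tsv")
  writeLines(dom_lines, dom_path, useBytes = TRUE)

  sent_terms <- unique(unlist(config$pools$sentiment, use.names = FALSE))
  swn <- c("# SentiWordNet-format synthetic sentiment lexicon",
           "# POS\tID\tPosScore\tNegScore\tSynsetTerms\tGloss")
  id <- 0
  for (t in sent_terms) {
    id <- id + 1
    swn <- c(swn, sprintf("a\t%08d\t0.625\t0.25\t%s#1\tsynthetic sense", id, t))
  }
  # second senses for the first three lemmas: subjectivity stays > 0.5
  for (t in utils::head(sent_terms, 3)) {
    id <- id + 1
    swn <- c(swn, sprintf("v\t%08d\t0.5\t0.25\t%s#2\tsynthetic second sense", id, t))
  }
  for (t in .distractor_lemmas) {
    id <- id + 1
    swn <- c(swn, sprintf("n\t%08d\t0.125\t0.125\t%s#1\tsynthetic distractor", id, t))
  }
  sent_path <- file.path(dir, "sentiment_lexicon.txt")
  writeLines(swn, sent_path, useBytes = TRUE)

  list(domain = load_domain_lexicon(dom_path),
       sentiment = load_sentiment_lexicon(sent_path),
       paths = list(domain = dom_path, sentiment = sent_path))
}

# unit log-probability matrix (units x classes) under the generator
.unit_log_probs <- function(config) {
  m <- length(config$classes)
  all_units <- unique(unlist(lapply(seq_len(m), function(j)
    unlist(.class_pools(config, j), use.names = FALSE)), use.names = FALSE))
  P <- matrix(0, length(all_units), m,
              dimnames = list(all_units, config$classes))
  for (j in seq_len(m)) {
    probs <- .cat_probs(config, j)
    pools <- .class_pools(config, j)
    for (cat in names(pools)) {
      pool <- pools[[cat]]
      if (length(pool) && probs[[cat]] > 0) {
        P[pool, j] <- P[pool, j] + probs[[cat]] / length(pool)
      }
    }
  }
  log(P)
}

#' Monte-Carlo Bayes-optimal accuracy of the generator
#'
#' Draws fresh messages from the generative model and classifies each with
#' the true-parameter posterior (class prior x Poisson length likelihood x
#' product of unit emission probabilities; ties toward class order).  The
#' resulting accuracy is an upper reference for any classifier trained on
#' data from the same configuration.
#'
#' @param config a [synth_config()].
#' @param n_mc number of Monte-Carlo messages (default 20000).
#' @param seed MC seed (independent of the corpus seed).
#' @return A list with `estimate`, `se` (binomial standard error), `n_mc`.
#' @export
bayes_optimal_accuracy <- function(config, n_mc = 20000, seed = 1) {
  stopifnot(inherits(config, "synth_config"), n_mc >= 1)
  logP <- .unit_log_probs(config)
  log_prior <- log(config$class_proportions)
  m <- length(config$classes)
  correct <- local_seed(seed, {
    cls <- sample.int(m, n_mc, replace = TRUE, prob = config$class_proportions)
    hits <- logical(n_mc)
    for (s in seq_len(n_mc)) {
      j <- cls[s]
      L <- stats::rpois(1, config$length_mean[j])
      units <- .emit_units(config, j, L)
      ll <- log_prior + stats::dpois(L, config$length_mean, log = TRUE)
      if (L > 0) {
        tab <- table(units)
        idx <- match(names(tab), rownames(logP))
        ll <- ll + as.numeric(as.numeric(tab) %*% logP[idx, , drop = FALSE])
      }
      hits[s] <- which.max(ll) == j   # which.max ties -> earliest class
    }
    hits
  })
  est <- mean(correct)
  list(estimate = est, se = sqrt(est * (1 - est) / n_mc), n_mc = n_mc)
}
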