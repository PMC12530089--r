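---
title: "Row-based raw-signal storage: formats, codecs and the acquisition simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Row-based raw-signal storage: formats, codecs and the acquisition simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigrow)
```

## The problem

Nanopore instruments emit a time series of ionic-current measurements
("raw signal", signed 16-bit ADC counts) for every molecule that transits
a pore. A production sequencing run produces millions of such reads, and
the two analysis access patterns differ sharply: *sequential* reading
(basecalling touches every read once, in file order) and *random* access
(duplex basecalling or signal browsing retrieves specific reads by ID).
`sigrow` implements a row-based container for this data — every field of a
read stored contiguously in one row — in an ASCII dialect (`.slow5`) and a
binary dialect (`.blow5`), plus the two pieces of machinery that make the
row layout competitive at scale: a read-ID index for single-seek random
access, and a two-pass writing strategy that parallelises acquisition
without interleaving rows. A deliberately minimal column-oriented,
chunk-interleaved container (`.colsig`) is included as a comparator so the
access-pattern consequences of layout can be measured inside one codebase.

## The read model

A read carries a unique text ID, a read-group ordinal, four calibration
fields, the signal, and auxiliary fields:

| field | type | meaning |
|---|---|---|
| `digitisation` | positive real | number of ADC levels |
| `offset` | real | calibration offset, ADC units |
| `range` | positive real | full-scale range, pA |
| `sampling_rate` | positive real | Hz |
| `raw_signal` | int16 vector | ADC counts |
| `channel_number`, `read_number`, `start_mux`, `start_time`, `median_before` | aux | run context |

Calibration maps counts to picoamperes as
`pA = (raw + offset) * range / digitisation`; the ratio
`range / digitisation` is the per-read *scale*. Read tables are tibbles
(one row per read, signal as a list-column), so they compose with dplyr.

```{r}
r <- list(raw_signal = c(-10L, 0L, 10L), digitisation = 8192,
          offset = 10, range = 819.2)
pa_convert(r)
```

## Signal compression

The binary dialect compresses signal with a zigzag-delta transform
followed by StreamVByte-style variable-byte packing, then (optionally)
whole-record zlib or zstd. Three choices here were genuinely open and are
fixed as follows:

* **Deltas wrap in int16 arithmetic.** The zigzag map is
  `z = (d << 1) XOR (d >> 15)`, i.e. 16-bit; computing the delta with
  int16 wrap-around guarantees every zigzag code fits a uint16, which is
  what makes the 2-byte StreamVByte variant (`svb16-zd`: 1 control bit per
  value, 8 values per control byte, 1–2 data bytes) total over all int16
  inputs. The 4-byte variant (`svb32-zd`: 2 control bits, 4 values per
  control byte, 1–4 data bytes) is kept for comparison.
* **The first value is a delta from zero**, stored through the same
  zigzag path — one code path, no special case.
* **Framing**: payloads begin with an unsigned 64-bit little-endian
  sample count, then the control-byte block (final-byte pad bits zero),
  then minimal-length little-endian data bytes. Compressed record blobs
  carry an 8-byte uncompressed-size prefix; codec `none` is the identity.

The implementation is scalar C++; equivalence, not SIMD throughput, is
the contract, and the test suite holds it to a naive scalar reference
plus exact round trips over random int16 arrays. For smooth signals
(first value and all deltas in [-64, 63]) `svb16-zd` provably spends
exactly one data byte per sample, which the suite asserts on constructed
fixtures.

## Container dialects

These dialects are self-consistent and fully documented here; they are
not byte-compatible with any external tool's container.

**ASCII** (`.slow5`): `#slow5_version x.y.z`, `#num_read_groups n`,
`@key<TAB>value-per-group` attribute lines, a `#`-prefixed column schema,
then one tab-separated row per read with the signal comma-joined in one
field. `.` is the missing sentinel (so a literal string value `.` cannot
be distinguished from missing — a documented dialect limitation). Floats
are written with the shortest representation that round-trips the exact
double, so ASCII conversion is bit-lossless.

**Binary** (`.blow5`): an 8-byte magic, version and codec bytes, a
compressed header block, then length-prefixed per-record-compressed rows
in write order, terminated by an end-of-file marker whose leading four
bytes are an invalid frame length (making truncation detection
unambiguous). All integers little-endian; doubles IEEE-754. Auxiliary
fields are serialized as a typed key/value block, so unknown columns
survive round trips. The index sidecar (`.blow5.idx`) stores
(ID, offset, framed length) triplets zlib-compressed, plus the data
file's size and a fingerprint of its first 4 KiB: a mismatch raises a
stale-index error, because a silent wrong-offset read is the worst
possible failure mode.

**Columnar comparator** (`.colsig`): each metadata attribute stored for
all reads contiguously; signal split into fixed-size chunks (default
102,400 samples, the conventional columnar default) tagged with read and
chunk ordinals, interleavable across reads (`round_robin` opens up to 4
reads concurrently, a deterministic stand-in for acquisition-order
interleaving, which real columnar writers do not document); a footer maps
reads to chunk locations and columns to byte regions. Retrieval is
index-free: pass 1 loads the footer into a look-up table, pass 2 performs
one seek per attribute column and per chunk for each requested read. That
seek asymmetry — one seek per read through the index versus
`columns + chunks` seeks per read for the walker — is the mechanism the
benchmark harness measures; both paths must return identical records.

## The benchmark harness

`bench_sequential()` and `bench_random()` time the load/decompress/parse
phase and then consume the data the way a basecaller's loader does:
fields accessed in loader order with narrowing conversions
(`sampling_rate` and `channel_number` to uint16 — out-of-range values are
conversion errors, keeping the conversion penalty honest), scale computed
as `range / digitisation`, and a per-read signal sum. The sums feed an
order-invariant FNV-1a digest; the digest must be identical across
formats, worker counts, batch sizes and codecs, and that invariance — not
any wall-clock number — is what the tests assert, because timings are
hardware properties. Batch size defaults to 1,000 reads. Peak memory is
read from the OS (`VmHWM`) and only reported. Dropping OS page caches
between runs is a manual runbook step (`/proc/sys/vm/drop_caches` as
root), deliberately not code: it needs privileges and is measurement
methodology, not algorithm.

## The acquisition simulator

`run_simulation()` mimics a multi-position instrument writing row-format
files in real time. Per position and acquisition tick (one chunk interval
= `chunk_size / sampling_rate` seconds, 40 s at the defaults), three task
pools run:

1. **acquisition** — every active channel produces up to one chunk of
   samples. Reads no longer than the chunk size (at 5 kHz and 400 bps a
   200,000-sample chunk spans ~16 kbases, so most reads qualify) are
   written directly to `pos<i>.blow5`; longer reads stream chunk by chunk
   into one temporary file per read. Boundary reads (exactly one chunk)
   go direct — they fit a single chunk buffer.
2. **merge** — completed temporary files are read whole, appended to the
   separate `pos<i>_merged.blow5`, and deleted. Long reads therefore land
   in completion order, naturally grouped by channel.
3. **read-back** — newly completed records are re-read and their signal
   summed, standing in for live basecalling.

The real-time constraint is made explicit, since "keeping up" needs a
deadline definition: a task warns when its wall time exceeds
`chunk_interval * time_dilation` seconds. `time_dilation` scales the
deadline — 1 is real time, larger values let a desk-scale test compress a
long run into seconds while preserving deadline semantics, and 0 makes
every deadline impossible (all tasks warn). `capacity_search()` raises
the position count until the first warning; a single warning fails a
configuration, and the largest clean count is the capacity. An injectable
deterministic throttle exists so capacity behaviour is testable without
depending on machine speed. The three pools are interleaved per-position
tasks in one R process rather than OS threads; per-position deadline
accounting is what the contract preserves. The memory budget is
`channels x chunk_size x bytes_per_sample` — 144,000 channels at a
200,000-sample chunk of 2-byte samples is ~54 GiB.

Channel occupancy defaults to 0.45 (the fraction of channels actively
producing signal); real duty cycles vary by run and are not standardised,
so it is a configuration knob and no acceptance behaviour depends on it.
Conservation is the simulator's core invariant: the samples of every
completed read appear in exactly one output file, contiguously, and the
ledger of generated samples equals the samples written. Shutdown deletes
temporaries of in-flight reads; re-running over a dirty output directory
fails loudly rather than double-writing. Simulated signal content is a
cheap deterministic integer pattern — the simulator exercises I/O and
timing, not pore physics.

## The synthetic generator

`generate_reads()` exists so every container, codec and harness path is
testable without any external download. Defaults: log-normal read lengths
with median 8,000 samples and sigma(log) = 1, clipped to [100, 2e6]
(a realistic long-read shape); signal as an integer-rounded two-component
Gaussian mixture around two pore current levels (means 480 and 760 ADC
counts, sd 40) — enough structure to exercise delta compression, with no
claim of biophysical realism; channels cycle 1..`n_channels` with
strictly monotone per-channel start times; ~5% of `median_before` values
are missing to exercise the sentinel paths. Identical configurations
generate byte-identical files. What passing tests on these fixtures shows
is exact container/codec fidelity and contract behaviour; what they do
not show is performance or compression ratios on real pore signal, whose
autocorrelation structure differs from the mixture model.

## Problem sizes used by the checks

The test suite runs round trips of 1,000 generated reads under all nine
codec combinations, a 10,000-array codec identity check against the
scalar reference, and a million-read random-access fixture from which a
seeded 50,000-ID sample is fetched both ways (index and walker). For the
million-read fixture the generator uses short reads (log-normal median 30
samples, bounds [8, 120]): the random-access contracts under test —
request-order equality with the sequential scan, one seek per fetched
read, walker seek ordering — depend on the number of records, not on
read length, and short reads keep the fixture around a hundred megabytes.
The simulator acceptance run uses 2 positions x 10 channels with a
500-sample chunk over 30 simulated seconds, time-dilated; capacity search
is exercised against an injected throttle with a known ceiling of 5.

## Known limitations

* No byte compatibility with external container implementations; this
  package's dialects are self-contained.
* The walker's pass 1 reads the footer rather than re-scanning every
  chunk header; files whose footer is corrupt but whose chunks are intact
  are recoverable in principle but not by this implementation.
* `record_compress()`'s zstd path requires the zstd library found at
  build time; when absent the codec reports a capability error naming it.
* The simulator multiplexes its pools onto one process; it preserves
  deadline accounting per position but cannot observe true I/O contention
  between positions the way independent OS threads would, so its absolute
  capacity numbers are optimistic and only the relative/ordering
  behaviour is asserted anywhere.
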