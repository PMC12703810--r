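# Naive complex multiplication (no intermediate NaN/Inf recovery) keeps the
# EPG recursion's std::complex arithmetic inlined; the simulation never
# produces non-finite intermediates.
PKG_CXXFLAGS = -fcx-limited-range
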