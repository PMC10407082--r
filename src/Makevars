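# The conda-forge cross compiler bundles a sysroot with a newer glibc
# than common container runtimes, so its objects fail to load; build
# with the system toolchain instead.
override CXX = g++ -std=gnu++17
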